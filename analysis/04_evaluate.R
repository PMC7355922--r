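#!/usr/bin/env Rscript
# Stage 4: lesion-level diagnostic accuracy of the selected model. ROC with
# a stratified percentile-bootstrap 95% band, the operating point at perfect
# sensitivity (every melanoma recommended for biopsy), and the screening
# arithmetic: specificity, number needed to treat before/after, and the
# percentage of benign biopsies avoided.

library(ramanscreen)

post <- data.table::fread("results/posteriors.csv", data.table = FALSE)
posteriors <- setNames(post$posterior, post$lesion_id)
labels <- setNames(post$label, post$lesion_id)

roc <- roc_curve(posteriors, labels)
cat(sprintf("lesion-level AUROC: %.3f\n", roc$auroc))

band <- bootstrap_roc_band(posteriors, labels, n_boot = 2000L, seed = 0L)
op <- full_sensitivity_operating_point(posteriors, labels)
sm <- screening_metrics(op$counts)
print(sm)
cat(sprintf("at the reported screening NNT range 6.0-30, %.1f%%-%.1f%% of biopsies are unnecessary\n",
            round(unnecessary_fraction(6.0), 1),
            round(unnecessary_fraction(30), 1)))

data.table::fwrite(data.frame(threshold = roc$thresholds,
                              sensitivity = roc$sensitivity,
                              specificity = roc$specificity),
                   "results/roc_points.csv")
jsonlite::write_json(
  list(auroc = roc$auroc,
       operating_point = list(threshold = op$threshold, tp = op$counts$tp,
                              fn = op$counts$fn, tn = op$counts$tn,
                              fp = op$counts$fp),
       screening = unclass(sm)[c("sensitivity", "specificity", "nnt_before",
                                 "nnt_after", "biopsies_avoided")],
       band = list(level = band$level, n_boot = band$n_boot)),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

ramanscreen:::plot_roc(roc, band, "results/roc.png")
pre <- read_spectra_table("results/preprocessed_spectra.csv",
                          "results/manifest.csv")
ramanscreen:::plot_scree(fit_pca(spectra_matrix(pre), 15L), "results/scree.png")
cat("wrote results/roc_points.csv, results/evaluation.json, results/roc.png, results/scree.png\n")
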