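#!/usr/bin/env Rscript
# Stage 3: leave-one-lesion-out PCA + ridge-logistic classification with the
# exhaustive PC-subset search: all 9,948 subsets of the first 15 PCs with at
# most 6 members (the one-in-ten rule for 60 lesions). Per fold, PCA is fit
# on the training lesions only and the held-out lesion is projected with the
# training rotation; the lesion posterior is the max over its measurements
# (OR rule).

library(ramanscreen)

pre <- read_spectra_table("results/preprocessed_spectra.csv",
                          "results/manifest.csv")
lt <- lesion_table(pre)

t0 <- proc.time()[["elapsed"]]
fs <- lolo_fold_scores(pre, n_pcs = 15L)
cat(sprintf("cached %d LOLOCV folds in %.1f s\n", length(fs$folds),
            proc.time()[["elapsed"]] - t0))

subsets <- enumerate_pc_subsets(15, 6)
t0 <- proc.time()[["elapsed"]]
sr <- search_best_subset(fs, subsets, reg = 1e-4)
cat(sprintf("searched %d PC subsets in %.1f s\n", length(subsets),
            proc.time()[["elapsed"]] - t0))
print(sr)

cv <- lolo_cv_predict(fs, sr$best_subset, reg = 1e-4)
post <- data.frame(lesion_id = names(cv$lesion_posterior),
                   label = lt$label[match(names(cv$lesion_posterior),
                                          lt$lesion_id)],
                   posterior = unname(cv$lesion_posterior))
data.table::fwrite(post, "results/posteriors.csv")

ord <- order(sr$auroc, decreasing = TRUE)[1:25]
top <- data.frame(subset = vapply(sr$subsets[ord], paste, "", collapse = "+"),
                  size = lengths(sr$subsets[ord]),
                  auroc = sr$auroc[ord])
data.table::fwrite(top, "results/subset_aurocs_top.csv")

jsonlite::write_json(
  list(best_subset = sr$best_subset, best_auroc = sr$best_auroc,
       n_subsets = length(subsets), n_tied_subsets = length(sr$ties),
       n_pcs = 15, max_subset_size = 6, reg = 1e-4),
  "results/best_model.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/posteriors.csv, results/subset_aurocs_top.csv, results/best_model.json\n")
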