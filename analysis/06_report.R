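#!/usr/bin/env Rscript
# Stage 6: assemble the stage outputs into the run-level metrics file and
# render the human-readable report (prediction-accuracy table + headline
# metrics), with a checksum guard on the posteriors file.

library(ramanscreen)

ev <- jsonlite::read_json("results/evaluation.json", simplifyVector = TRUE)
nl <- jsonlite::read_json("results/null_summary.json", simplifyVector = TRUE)
bm <- jsonlite::read_json("results/best_model.json", simplifyVector = TRUE)
post <- data.table::fread("results/posteriors.csv", data.table = FALSE)

metrics <- list(
  config_hash = unname(tools::md5sum("results/best_model.json")),
  seed = 0L,
  n_lesions = nrow(post),
  n_melanoma = sum(post$label == "melanoma"),
  n_measurements = nrow(data.table::fread("results/manifest.csv")),
  n_subsets = bm$n_subsets,
  best_subset = bm$best_subset,
  best_auroc = bm$best_auroc,
  operating_point = ev$operating_point,
  screening = ev$screening,
  randomization = list(n_replicates = nl$n_replicates,
                       n_positive = nl$n_positive,
                       mean_best_auroc = nl$mean_best_auroc,
                       exceedance = nl$exceedance, cutoff = nl$cutoff),
  posteriors_md5 = unname(tools::md5sum("results/posteriors.csv")))
jsonlite::write_json(metrics, "results/metrics.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

path <- make_report("results")
cat(readLines(path), sep = "\n")
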