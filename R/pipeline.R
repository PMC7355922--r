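# End-to-end driver: simulate (or ingest) -> preprocess -> classify ->
# evaluate -> randomization null, with all artifacts written to a run
# directory. One root seed governs a run; the simulate / bootstrap /
# randomize stages draw from named sub-streams so they can be rerun
# independently.

#' Configuration for a full pipeline run
#'
#' @param synthetic A [synthetic_config()]; its seed is overridden by the
#'   run seed's simulate sub-stream.
#' @param preprocess A [preprocess_config()].
#' @param n_pcs,max_subset_size PC search space (first `n_pcs` components,
#'   subsets up to `max_subset_size`).
#' @param reg Ridge penalty for logistic fits.
#' @param n_boot Bootstrap replicates for the ROC band.
#' @param rand_replicates,rand_cutoff Randomization-null replicates and the
#'   AUROC exceedance cutoff.
#' @param rand_n_pcs,rand_max_subset_size Subset-space cap for the
#'   randomization null (each replicate repeats the full search, so the
#'   default caps the space to keep a desk run tractable; set to
#'   `n_pcs`/`max_subset_size` to mirror the real-label search exactly).
#' @param seed Root seed for the run.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       preprocess = preprocess_config(),
                       n_pcs = 15L, max_subset_size = 6L, reg = 1e-4,
                       n_boot = 2000L,
                       rand_replicates = 99L, rand_cutoff = 0.9,
                       rand_n_pcs = 15L, rand_max_subset_size = 2L,
                       seed = 0L) {
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 n_pcs = as.integer(n_pcs),
                 max_subset_size = as.integer(max_subset_size), reg = reg,
                 n_boot = as.integer(n_boot),
                 rand_replicates = as.integer(rand_replicates),
                 rand_cutoff = rand_cutoff,
                 rand_n_pcs = as.integer(rand_n_pcs),
                 rand_max_subset_size = as.integer(rand_max_subset_size),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or ingests `dataset`), preprocesses it, runs the
#' LOLOCV PC-subset search, evaluates the best model (ROC + bootstrap band,
#' perfect-sensitivity operating point, screening metrics), and runs the
#' label-randomization null. Artifacts written to `out_dir`: preprocessed
#' spectra/manifest CSVs, QC CSV, per-lesion posteriors CSV, `metrics.json`,
#' ROC / scree / null-histogram figures, and a timing log. `metrics.json`
#' contains no timestamps, so a rerun with the same config is byte-identical.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param dataset Optional raw `spectra_dataset` to analyse instead of a
#'   simulated cohort.
#' @return Invisibly, the metrics list.
#' @export
run_full_pipeline <- function(cfg, out_dir, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  t_stage <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log_line(con, "[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  raw <- t_stage({
    if (is.null(dataset)) {
      cfg$synthetic$seed <- child_seed(cfg$seed, 0L, stream = 1L)
      generate_cohort(cfg$synthetic)$dataset
    } else dataset
  }, "simulate")

  pre <- t_stage(preprocess_dataset(raw, cfg$preprocess), "preprocess")
  write_spectra_table(pre, file.path(out_dir, "preprocessed_spectra.csv"),
                      file.path(out_dir, "manifest.csv"))
  data.table::fwrite(attr(pre, "qc"), file.path(out_dir, "qc.csv"))

  lt <- lesion_table(pre)
  if (length(unique(lt$label)) < 2L) {
    stop_rs("stage evaluate: dataset has a single class; classification requires both labels",
            class = "evaluation_error")
  }

  fs <- t_stage(lolo_fold_scores(pre, cfg$n_pcs), "fold_scores")
  subsets <- enumerate_pc_subsets(cfg$n_pcs, cfg$max_subset_size)
  sr <- t_stage(search_best_subset(fs, subsets, cfg$reg), "subset_search")
  cv <- lolo_cv_predict(fs, sr$best_subset, cfg$reg)

  post <- data.frame(lesion_id = names(cv$lesion_posterior),
                     label = lt$label[match(names(cv$lesion_posterior),
                                            lt$lesion_id)],
                     posterior = unname(cv$lesion_posterior))
  post_path <- file.path(out_dir, "posteriors.csv")
  data.table::fwrite(post, post_path)

  roc <- roc_curve(cv$lesion_posterior, stats::setNames(lt$label, lt$lesion_id))
  band <- t_stage(bootstrap_roc_band(cv$lesion_posterior,
                                     stats::setNames(lt$label, lt$lesion_id),
                                     n_boot = cfg$n_boot, seed = cfg$seed),
                  "bootstrap")
  op <- full_sensitivity_operating_point(cv$lesion_posterior,
                                         stats::setNames(lt$label, lt$lesion_id))
  sm <- screening_metrics(op$counts)

  rand <- t_stage(randomization_test(
    pre, enumerate_pc_subsets(cfg$rand_n_pcs, cfg$rand_max_subset_size),
    n_replicates = cfg$rand_replicates,
    n_positive = sum(lt$label == "melanoma"),
    reg = cfg$reg, seed = cfg$seed, n_pcs = cfg$n_pcs, fold_scores = fs),
    "randomization")

  pca_full <- fit_pca(spectra_matrix(pre), cfg$n_pcs)

  metrics <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_lesions = nrow(lt),
    n_melanoma = sum(lt$label == "melanoma"),
    n_measurements = n_measurements(pre),
    n_subsets = length(subsets),
    best_subset = sr$best_subset,
    best_auroc = sr$best_auroc,
    n_tied_subsets = length(sr$ties),
    variance_captured_pct = 100 * sum(pca_full$explained_variance_fraction),
    operating_point = list(threshold = op$threshold,
                           tp = op$counts$tp, fn = op$counts$fn,
                           tn = op$counts$tn, fp = op$counts$fp),
    screening = unclass(sm)[c("sensitivity", "specificity", "nnt_before",
                              "nnt_after", "biopsies_avoided")],
    randomization = list(n_replicates = rand$n_replicates,
                         n_positive = rand$n_positive,
                         mean_best_auroc = mean(rand$replicate_aurocs),
                         exceedance = exceedance(rand, cfg$rand_cutoff),
                         cutoff = cfg$rand_cutoff),
    posteriors_md5 = unname(tools::md5sum(post_path)))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  t_stage({
    plot_roc(roc, band, file.path(out_dir, "roc.png"))
    plot_scree(pca_full, file.path(out_dir, "scree.png"))
    plot_null_hist(rand, cfg$rand_cutoff,
                   file.path(out_dir, "randomization_hist.png"))
  }, "figures")

  invisible(metrics)
}

plot_roc <- function(roc, band, path) {
  df <- data.frame(fpr = 1 - roc$specificity, tpr = roc$sensitivity)
  bd <- data.frame(fpr = 1 - band$spec_grid, lo = band$lower, hi = band$upper)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_ribbon(data = bd,
                         ggplot2::aes(x = fpr, ymin = lo, ymax = hi),
                         inherit.aes = FALSE, fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Lesion-level ROC (AUROC %.3f, %g%% band)",
                                  roc$auroc, 100 * band$level)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4.5, dpi = 150)
}

plot_scree <- function(pca, path) {
  df <- data.frame(pc = seq_along(pca$explained_variance_fraction),
                   evf = 100 * pca$explained_variance_fraction)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = pc, y = evf)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Principal component", y = "Variance explained (%)",
                  title = sprintf("Scree plot (first %d PCs: %.1f%%)",
                                  nrow(df), sum(df$evf))) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 150)
}

plot_null_hist <- function(rand, cutoff, path) {
  df <- data.frame(auroc = rand$replicate_aurocs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = auroc)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0,
                            fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = cutoff, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "Best-over-subsets AUROC (random labels)", y = "Replicates",
                  title = sprintf("Randomization null (%d replicates, P(AUROC > %.2g) = %.3f)",
                                  rand$n_replicates, cutoff,
                                  mean(rand$replicate_aurocs > cutoff))) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 150)
}

#' Render a human-readable run report
#'
#' Reads the artifacts of a completed [run_full_pipeline()] directory and
#' writes `report.md` with a prediction-accuracy table (per class: lesions,
#' correct predictions, false predictions, potential biopsies) and the
#' headline metrics. The posteriors file is checked against the checksum
#' recorded in `metrics.json`; a mismatch produces a warning in the report
#' and on the console.
#'
#' @param run_dir A completed run directory.
#' @return Invisibly, the path to `report.md`.
#' @export
make_report <- function(run_dir) {
  need <- c("metrics.json", "posteriors.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop_rs("run directory '%s' is missing artifact(s): %s", run_dir,
            paste(missing, collapse = ", "), class = "report_error")
  }
  metrics <- jsonlite::read_json(file.path(run_dir, "metrics.json"),
                                 simplifyVector = TRUE)
  post_path <- file.path(run_dir, "posteriors.csv")
  checksum_ok <- identical(unname(tools::md5sum(post_path)),
                           metrics$posteriors_md5)
  if (!checksum_ok) {
    warning("posteriors.csv checksum does not match metrics.json; file may have been modified")
  }
  op <- metrics$operating_point
  tab <- data.frame(
    lesion_type = c("Pigmented lesions", "Melanoma", "Total"),
    lesions = c(op$tn + op$fp, op$tp + op$fn, op$tn + op$fp + op$tp + op$fn),
    correct = c(op$tn, op$tp, op$tn + op$tp),
    false_predictions = c(op$fp, op$fn, op$fp + op$fn),
    potential_biopsies = c(op$fp, op$tp, op$fp + op$tp))
  lines <- c(
    "# Run report",
    "",
    sprintf("- Config hash: `%s`; seed %d", metrics$config_hash, metrics$seed),
    sprintf("- Cohort: %d lesions (%d melanoma), %d measurements",
            metrics$n_lesions, metrics$n_melanoma, metrics$n_measurements),
    sprintf("- Best PC subset: {%s} of %d searched; lesion-level AUROC %.3f",
            paste(metrics$best_subset, collapse = ", "), metrics$n_subsets,
            metrics$best_auroc),
    sprintf("- At perfect sensitivity: specificity %.1f%%, NNT %.1f -> %.1f, %.1f%% of benign biopsies avoided",
            metrics$screening$specificity, metrics$screening$nnt_before,
            metrics$screening$nnt_after, metrics$screening$biopsies_avoided),
    sprintf("- Randomization null: mean best AUROC %.3f over %d replicates; P(AUROC > %.2g) = %.3f",
            metrics$randomization$mean_best_auroc,
            metrics$randomization$n_replicates,
            metrics$randomization$cutoff, metrics$randomization$exceedance),
    if (!checksum_ok) "- WARNING: posteriors.csv checksum mismatch" else NULL,
    "",
    "## Prediction accuracy",
    "",
    "| Lesion type | Lesions | Correct predictions | False predictions | Potential biopsies |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %d (%.1f%%) | %d | %d |",
            tab$lesion_type, tab$lesions, tab$correct,
            100 * tab$correct / tab$lesions, tab$false_predictions,
            tab$potential_biopsies))
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
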