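# Lesion-level diagnostic evaluation: ROC/AUROC, bootstrap confidence band,
# the operating point at perfect sensitivity, and screening arithmetic
# (number needed to treat, biopsies avoided).

align_labels <- function(posteriors, labels) {
  if (!is.null(names(posteriors)) && !is.null(names(labels))) {
    labels <- labels[names(posteriors)]
  }
  stopifnot(length(posteriors) == length(labels))
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop_rs("both classes must be present for evaluation",
            class = "evaluation_error")
  }
  list(p = as.numeric(posteriors), y = y)
}

#' Lesion-level ROC curve
#'
#' Thresholds are the unique posterior values in descending order, preceded
#' by a +Inf sentinel; at threshold `t` a lesion is called melanoma when its
#' posterior is `>= t` (ties are biopsy-recommended). AUROC is the trapezoid
#' area, which equals the tie-corrected Mann-Whitney statistic.
#'
#' @param posteriors Named numeric vector of per-lesion melanoma
#'   probabilities.
#' @param labels Lesion labels (aligned by name when both are named).
#' @return A `roc_result`: `thresholds`, `sensitivity`, `specificity`,
#'   `auroc`.
#' @export
roc_curve <- function(posteriors, labels) {
  al <- align_labels(posteriors, labels)
  thr <- c(Inf, sort(unique(al$p), decreasing = TRUE))
  n1 <- sum(al$y == 1); n0 <- sum(al$y == 0)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- al$p >= thr[i]
    sens[i] <- sum(pred & al$y == 1) / n1
    spec[i] <- sum(!pred & al$y == 0) / n0
  }
  x <- 1 - spec
  auroc <- trapz_area(x, sens)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auroc = auroc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUROC %.4f over %d thresholds>\n",
              x$auroc, length(x$thresholds)))
  invisible(x)
}

sens_at_spec_grid <- function(roc, spec_grid) {
  vapply(spec_grid, function(s) {
    ok <- roc$specificity >= s - 1e-12
    if (any(ok)) max(roc$sensitivity[ok]) else 0
  }, 0)
}

#' Bootstrap confidence band for the ROC curve
#'
#' Stratified percentile bootstrap over lesions: within each class, lesions
#' are resampled with replacement; the band is the percentile envelope of
#' sensitivity on a fixed specificity grid. Stratification guarantees both
#' classes in every replicate. Deterministic given `seed`.
#'
#' @param posteriors,labels As in [roc_curve()].
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @param spec_grid Specificity grid for the band.
#' @return A `roc_band`: `spec_grid`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_roc_band <- function(posteriors, labels, n_boot = 2000L,
                               level = 0.95, seed = 1L,
                               spec_grid = seq(0, 1, by = 0.01)) {
  al <- align_labels(posteriors, labels)
  idx1 <- which(al$y == 1); idx0 <- which(al$y == 0)
  set.seed(child_seed(seed, 0L, stream = 2L))
  S <- matrix(NA_real_, nrow = n_boot, ncol = length(spec_grid))
  for (b in seq_len(n_boot)) {
    take <- c(sample(idx1, length(idx1), replace = TRUE),
              sample(idx0, length(idx0), replace = TRUE))
    roc <- roc_curve(al$p[take], al$y[take])
    S[b, ] <- sens_at_spec_grid(roc, spec_grid)
  }
  alpha <- (1 - level) / 2
  structure(list(spec_grid = spec_grid,
                 lower = apply(S, 2L, quantile, probs = alpha, names = FALSE),
                 upper = apply(S, 2L, quantile, probs = 1 - alpha, names = FALSE),
                 level = level, n_boot = n_boot),
            class = "roc_band")
}

#' Operating point at perfect sensitivity
#'
#' The threshold is the minimum melanoma posterior, so every melanoma is
#' recommended for biopsy; the resulting specificity is the maximum
#' achievable at sensitivity 1.0. A pigmented lesion tied exactly with the
#' threshold counts as a false positive (the `>=` call rule is conservative
#' for screening).
#'
#' @param posteriors,labels As in [roc_curve()].
#' @return List: `threshold` and `counts` (a `confusion_counts` object with
#'   `tp`, `fn`, `tn`, `fp`).
#' @export
full_sensitivity_operating_point <- function(posteriors, labels) {
  al <- align_labels(posteriors, labels)
  thr <- min(al$p[al$y == 1])
  pred <- al$p >= thr
  counts <- confusion_counts(tp = sum(pred & al$y == 1),
                             fn = sum(!pred & al$y == 1),
                             tn = sum(!pred & al$y == 0),
                             fp = sum(pred & al$y == 0))
  list(threshold = thr, counts = counts)
}

#' Lesion-level confusion counts
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "confusion_counts")
}

#' Screening metrics from confusion counts
#'
#' NNT (number needed to treat / biopsy) is biopsied lesions per detected
#' melanoma: before the classifier every lesion is biopsied
#' (`(tp+fn+tn+fp)/(tp+fn)`); after, only classifier-positive lesions are
#' (`(tp+fp)/tp`). Values are stored at full precision; the print method
#' rounds to one decimal.
#'
#' @param counts A [confusion_counts()].
#' @return A `screening_metrics` object: `sensitivity`, `specificity`
#'   (percent), `nnt_before`, `nnt_after`, `biopsies_avoided` (percent),
#'   `nnt_after_defined`.
#' @export
screening_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_mel <- counts$tp + counts$fn
  n_pig <- counts$tn + counts$fp
  if (n_mel == 0L) {
    stop_rs("no melanoma lesions: NNT undefined", class = "evaluation_error")
  }
  total <- n_mel + n_pig
  ok <- counts$tp > 0L
  structure(list(
    sensitivity = 100 * counts$tp / n_mel,
    specificity = if (n_pig > 0L) 100 * counts$tn / n_pig else NA_real_,
    nnt_before = total / n_mel,
    nnt_after = if (ok) (counts$tp + counts$fp) / counts$tp else NA_real_,
    biopsies_avoided = if (n_pig > 0L) 100 * counts$tn / n_pig else NA_real_,
    nnt_after_defined = ok),
    class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf(paste0("screening metrics: sensitivity %.1f%%, specificity %.1f%%,\n",
                     "  NNT %.1f -> %.1f, biopsies avoided %.1f%%\n"),
              x$sensitivity, x$specificity, x$nnt_before, x$nnt_after,
              x$biopsies_avoided))
  invisible(x)
}

#' Fraction of biopsies that are unnecessary at a given NNT
#'
#' If NNT lesions must be biopsied per confirmed melanoma, `100 * (1 - 1/NNT)`
#' percent of those biopsies find no melanoma.
#'
#' @param nnt Number needed to treat (`>= 1`).
#' @return Percentage at full precision (round to one decimal for display).
#' @export
unnecessary_fraction <- function(nnt) {
  if (any(nnt < 1)) stop_rs("NNT must be >= 1", class = "domain_error")
  100 * (1 - 1 / nnt)
}
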