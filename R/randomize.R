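# Label-randomization null: randomly reassign n_positive lesions to the
# melanoma class, rerun the full best-over-subsets search, and summarize the
# null distribution of the maximal AUROC. PCA is unsupervised, so the cached
# per-fold projections are reused across permutations (asserted by test).

#' Randomly permute class labels over lesions
#'
#' Draws `n_positive` lesions uniformly at random to carry the melanoma
#' label; all others become pigmented. Spectra are untouched and the input
#' dataset is not modified.
#'
#' @param ds A `spectra_dataset`.
#' @param n_positive Number of lesions assigned to the melanoma class.
#' @param seed Optional seed for the draw (uses current RNG state if `NULL`).
#' @return A new `spectra_dataset` with permuted labels.
#' @export
permute_class_labels <- function(ds, n_positive, seed = NULL) {
  n <- nrow(ds$lesions)
  if (n_positive <= 0L || n_positive >= n) {
    stop_rs("n_positive must be in 1..%d", n - 1L, class = "config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- sample.int(n, n_positive)
  ds$lesions$label <- ifelse(seq_len(n) %in% pos, "melanoma", "pigmented")
  ds
}

# Draw in a canonical (sorted) lesion ordering so a given seed labels the
# same lesions regardless of dataset row order.
random_label_draw <- function(lesion_ids, n_positive) {
  canonical <- sort(lesion_ids)
  pos <- canonical[sample.int(length(canonical), n_positive)]
  ifelse(lesion_ids %in% pos, "melanoma", "pigmented")
}

#' Label-randomization test for the best-over-subsets AUROC
#'
#' Each replicate assigns `n_positive` of the lesions to the melanoma class
#' at random, reruns the full PC-subset search (mirroring the analysis of the
#' real labels, so the comparison is fair to selection optimism), and records
#' the maximal lesion-level AUROC. Fold PCA projections are computed once and
#' reused: labels enter only the logistic stage.
#'
#' @param ds A preprocessed `spectra_dataset`.
#' @param subsets List of PC-index vectors searched per replicate.
#' @param n_replicates Number of random label assignments.
#' @param n_positive Lesions per replicate assigned to the melanoma class.
#' @param reg Ridge penalty for the logistic fits.
#' @param seed Root seed; each replicate uses a derived sub-seed.
#' @param n_pcs Components cached per fold.
#' @param fold_scores Optional precomputed [lolo_fold_scores()] cache.
#' @return A `randomization_summary`: `replicate_aurocs`, `best_subsets`,
#'   `n_replicates`, `n_positive`, `seed`, `n_failed`.
#' @export
randomization_test <- function(ds, subsets, n_replicates = 99L,
                               n_positive = 7L, reg = 1e-4, seed = 0L,
                               n_pcs = 15L, fold_scores = NULL) {
  if (length(subsets) == 0L) stop_rs("empty subset list", class = "config_error")
  fs <- fold_scores %||% lolo_fold_scores(ds, n_pcs)
  n_lesions <- length(fs$lesion_ids)
  if (n_positive <= 0L || n_positive >= n_lesions) {
    stop_rs("n_positive must be in 1..%d", n_lesions - 1L,
            class = "config_error")
  }
  aurocs <- numeric(n_replicates)
  best <- vector("list", n_replicates)
  n_failed <- 0L
  r <- 0L
  attempt <- 0L
  while (r < n_replicates) {
    attempt <- attempt + 1L
    if (attempt > 3L * n_replicates) {
      stop_rs("too many failed randomization replicates (%d)", n_failed,
              class = "internal_error")
    }
    set.seed(child_seed(seed, attempt, stream = 3L))
    labels <- random_label_draw(fs$lesion_ids, n_positive)
    sr <- tryCatch(search_best_subset(fs, subsets, reg, lesion_labels = labels),
                   ramanscreen_error = function(e) NULL)
    if (is.null(sr)) {
      n_failed <- n_failed + 1L
      next
    }
    r <- r + 1L
    aurocs[r] <- sr$best_auroc
    best[[r]] <- sr$best_subset
  }
  structure(list(replicate_aurocs = aurocs, best_subsets = best,
                 n_replicates = as.integer(n_replicates),
                 n_positive = as.integer(n_positive),
                 seed = as.integer(seed), n_failed = n_failed),
            class = "randomization_summary")
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf("<randomization_summary: %d replicates (%d positive labels), mean best AUROC %.3f, max %.3f>\n",
              x$n_replicates, x$n_positive, mean(x$replicate_aurocs),
              max(x$replicate_aurocs)))
  invisible(x)
}

#' Exceedance fraction of the null AUROC distribution
#'
#' Fraction of replicate best-over-subsets AUROCs strictly greater than
#' `cutoff`.
#'
#' @param summary A [randomization_test()] result.
#' @param cutoff AUROC cutoff.
#' @return Fraction in \[0, 1\].
#' @export
exceedance <- function(summary, cutoff) {
  mean(summary$replicate_aurocs > cutoff)
}
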