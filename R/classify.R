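# PCA + ridge-logistic classification under leave-one-lesion-out
# cross-validation (LOLOCV) with exhaustive PC-subset search.

#' Fit a PCA model to a spectra matrix
#'
#' Mean-centered SVD (no variance scaling — standard for area-normalized
#' spectra). Sign convention: each component's largest-magnitude loading is
#' positive. If the matrix is rank deficient below `n_components`, fewer
#' components are returned with attribute `rank_deficient = TRUE`.
#'
#' @param X Numeric matrix, observations x wavenumbers.
#' @param n_components Number of components requested
#'   (`<= min(nrow(X) - 1, ncol(X))`).
#' @return A `pca_model`: `mean`, `loadings` (components x wavenumbers),
#'   `explained_variance_fraction`, `n_components`.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop_rs("PCA needs at least 2 rows", class = "shape_error")
  if (n_components > min(n - 1L, p)) {
    stop_rs("n_components = %d exceeds min(nrow - 1, ncol) = %d",
            n_components, min(n - 1L, p), class = "config_error")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(n, p))
  d2 <- sv$d^2
  evf <- d2 / sum(d2)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {   # deterministic sign: largest |loading| positive
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  out <- structure(list(mean = mu, loadings = loadings,
                        explained_variance_fraction = evf[seq_len(k)],
                        n_components = k),
                   class = "pca_model")
  attr(out, "rank_deficient") <- k < n_components
  out
}

#' Project spectra onto a fitted PCA model
#'
#' `scores = (X - mean) %*% t(loadings)`; nothing is refit, so held-out data
#' use exactly the training rotation.
#'
#' @param model A `pca_model`.
#' @param X Matrix (or vector) with the model's number of wavenumbers.
#' @return Score matrix, observations x components.
#' @export
project <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$mean)) {
    stop_rs("projection input has %d columns, model expects %d",
            ncol(X), length(model$mean), class = "shape_error")
  }
  sweep(X, 2L, model$mean) %*% t(model$loadings)
}

#' Enumerate candidate PC subsets
#'
#' All non-empty subsets of `{1..n_pcs}` with at most `max_size` elements,
#' ordered by (size, lexicographic). The defaults reflect the one-in-ten
#' rule for a 60-lesion cohort: up to 6 PCs from the first 15.
#'
#' @param n_pcs Number of leading PCs in the search space.
#' @param max_size Maximum subset size.
#' @return List of strictly increasing integer vectors.
#' @export
enumerate_pc_subsets <- function(n_pcs = 15L, max_size = 6L) {
  n_pcs <- as.integer(n_pcs); max_size <- as.integer(max_size)
  if (n_pcs < 1L || max_size < 1L || max_size > n_pcs) {
    stop_rs("need 1 <= max_size <= n_pcs", class = "config_error")
  }
  out <- list()
  for (k in seq_len(max_size)) {
    cmb <- combn(n_pcs, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

#' Fit a ridge-penalized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood minus `reg * ||coefficients||^2`
#' (intercept unpenalized) by Newton's method, to gradient infinity-norm
#' below `tol`.
#'
#' @param Z Feature matrix (observations x features).
#' @param y Labels: 0/1, logical, or `"melanoma"`/`"pigmented"` (melanoma
#'   is the positive class).
#' @param reg Ridge penalty (>= 0). The tiny default keeps coefficients
#'   finite under perfect separation without changing probability rankings.
#' @param max_iter,tol Newton iteration controls.
#' @return A `logistic_model`: `intercept`, `coefficients`, `reg`,
#'   `converged`, `n_iter`.
#' @export
fit_logistic <- function(Z, y, reg = 1e-4, max_iter = 100L, tol = 1e-8) {
  Z <- as.matrix(Z)
  y <- as_binary_labels(y)
  if (length(y) != nrow(Z)) {
    stop_rs("labels length %d != %d rows", length(y), nrow(Z),
            class = "shape_error")
  }
  if (length(unique(y)) < 2L) {
    stop_rs("both classes must be present to fit a classifier",
            class = "fit_error")
  }
  if (reg < 0) stop_rs("reg must be >= 0", class = "config_error")
  fit <- cpp_ridge_logit(cbind(1, Z), y, reg, as.integer(max_iter), tol)
  if (!fit$converged) {
    stop_rs("logistic fit did not converge in %d iterations (gradient norm %.2e); data may be separable with reg = 0",
            max_iter, fit$grad_norm, class = "fit_error")
  }
  structure(list(intercept = fit$beta[1], coefficients = fit$beta[-1],
                 reg = reg, converged = fit$converged, n_iter = fit$n_iter),
            class = "logistic_model")
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  eta <- object$intercept + drop(newdata %*% object$coefficients)
  1 / (1 + exp(-eta))
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- normalize_label(y)
    as.numeric(y == "melanoma")
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) {
      stop_rs("numeric labels must be 0/1", class = "format_error")
    }
    y
  }
}

#' Cache per-fold PCA projections for LOLOCV
#'
#' For each lesion, PCA is fit on the spectra of all other lesions and the
#' first `n_pcs` training and held-out scores are cached, so the PCA (which
#' is label-free) is computed once per fold and reused across every PC subset
#' and every label permutation. Results must — and in the tests do — equal a
#' naive per-subset recomputation.
#'
#' @param ds A preprocessed `spectra_dataset` with at least 3 lesions.
#' @param n_pcs Number of leading components cached per fold.
#' @return A `lolo_fold_scores` object: per-fold train/test score matrices
#'   plus lesion/label bookkeeping.
#' @export
lolo_fold_scores <- function(ds, n_pcs = 15L) {
  lt <- lesion_table(ds)
  if (nrow(lt) < 3L) stop_rs("need at least 3 lesions", class = "config_error")
  M <- spectra_matrix(ds)
  meas_lesion <- ds$measurements$lesion_id
  truncated <- character(0)
  folds <- vector("list", nrow(lt))
  for (f in seq_len(nrow(lt))) {
    test_idx <- which(meas_lesion == lt$lesion_id[f])
    train_idx <- setdiff(seq_len(nrow(M)), test_idx)
    k <- min(n_pcs, length(train_idx) - 1L, ncol(M))
    if (k < n_pcs) truncated <- c(truncated, lt$lesion_id[f])
    pca <- fit_pca(M[train_idx, , drop = FALSE], k)
    folds[[f]] <- list(
      lesion_id = lt$lesion_id[f],
      train_idx = train_idx, test_idx = test_idx,
      train_scores = project(pca, M[train_idx, , drop = FALSE]),
      test_scores = project(pca, M[test_idx, , drop = FALSE]))
  }
  structure(list(folds = folds, n_pcs = n_pcs,
                 lesion_ids = lt$lesion_id, lesion_labels = lt$label,
                 meas_lesion = meas_lesion,
                 measurement_ids = ds$measurements$measurement_id),
            class = "lolo_fold_scores")
}

fold_label_vectors <- function(fs, lesion_labels) {
  lab <- as_binary_labels(lesion_labels)
  names(lab) <- fs$lesion_ids
  meas_y <- lab[fs$meas_lesion]
  lapply(fs$folds, function(f) unname(meas_y[f$train_idx]))
}

check_fold_classes <- function(fs, ys) {
  for (f in seq_along(ys)) {
    if (length(unique(ys[[f]])) < 2L) {
      stop_rs("fold for lesion '%s' has a single class in training",
              fs$folds[[f]]$lesion_id, class = "fit_error")
    }
  }
}

subset_matrix <- function(subsets, n_avail) {
  sizes <- lengths(subsets)
  if (any(sizes == 0L)) stop_rs("empty PC subset", class = "config_error")
  mx <- max(unlist(subsets))
  if (mx > n_avail) {
    stop_rs("subset index %d exceeds cached components (%d)", mx, n_avail,
            class = "config_error")
  }
  m <- matrix(0L, nrow = length(subsets), ncol = max(sizes))
  for (i in seq_along(subsets)) m[i, seq_len(sizes[i])] <- as.integer(subsets[[i]])
  list(mat = m, sizes = as.integer(sizes))
}

# Standardize cached fold scores by the training-fold standard deviation of
# each component. Area-normalized spectra give PC scores of order 1e-3, on
# which a fixed ridge penalty would act wildly differently than on O(1)
# features; standardizing puts the penalty on a meaningful scale. The test
# data use the training SDs (no leakage).
standardize_folds <- function(fs) {
  lapply(fs$folds, function(f) {
    sds <- apply(f$train_scores, 2L, sd)
    sds[sds < 1e-300] <- 1
    list(train = sweep(f$train_scores, 2L, sds, `/`),
         test = sweep(f$test_scores, 2L, sds, `/`))
  })
}

run_subset_search_cpp <- function(fs, subsets, reg, lesion_labels) {
  ys <- fold_label_vectors(fs, lesion_labels)
  check_fold_classes(fs, ys)
  n_avail <- min(vapply(fs$folds, function(f) ncol(f$train_scores), 0L))
  sm <- subset_matrix(subsets, n_avail)
  std <- standardize_folds(fs)
  res <- cpp_subset_search(lapply(std, `[[`, "train"),
                           lapply(std, `[[`, "test"),
                           ys, sm$mat, sm$sizes, reg, 200L, 1e-8)
  test_meas <- unlist(lapply(fs$folds, function(f) fs$measurement_ids[f$test_idx]))
  colnames(res$probs) <- test_meas
  res$test_fold <- rep(seq_along(fs$folds),
                       vapply(fs$folds, function(f) length(f$test_idx), 0L))
  res
}

#' Leave-one-lesion-out predictions for one PC subset
#'
#' Per fold, a ridge-logistic model is fit on the training spectra (every
#' spectrum carries its lesion's label, all spectra weighted equally) and the
#' held-out lesion's spectra receive probabilities. PC scores are
#' standardized by the training fold's per-component standard deviation
#' before the logistic stage, so the ridge penalty acts on a scale-free
#' feature space; held-out scores use the training SDs. The lesion posterior
#' is the maximum over its measurements — the OR rule.
#'
#' @param fs A [lolo_fold_scores()] cache.
#' @param subset Integer vector of 1-based PC indices.
#' @param reg Ridge penalty.
#' @param lesion_labels Optional label override (one per lesion, in
#'   `fs$lesion_ids` order); defaults to the dataset labels.
#' @return A `cv_predictions` object: `spectrum_prob` (named),
#'   `lesion_posterior` (named), `n_folds`.
#' @export
lolo_cv_predict <- function(fs, subset, reg = 1e-4, lesion_labels = NULL) {
  lesion_labels <- lesion_labels %||% fs$lesion_labels
  res <- run_subset_search_cpp(fs, list(as.integer(subset)), reg, lesion_labels)
  probs <- drop(res$probs)
  names(probs) <- colnames(res$probs)
  posterior <- vapply(split(probs, fs$meas_lesion[match(names(probs), fs$measurement_ids)]),
                      max, 0)
  posterior <- posterior[fs$lesion_ids]
  structure(list(spectrum_prob = probs, lesion_posterior = posterior,
                 n_folds = length(fs$folds)),
            class = "cv_predictions")
}

lesion_posterior_matrix <- function(res, n_lesions) {
  P <- matrix(-Inf, nrow = nrow(res$probs), ncol = n_lesions)
  for (f in seq_len(n_lesions)) {
    cols <- which(res$test_fold == f)
    P[, f] <- do.call(pmax, lapply(cols, function(j) res$probs[, j]))
  }
  P
}

# Tie-corrected Mann-Whitney AUROC; by the trapezoid/rank identity (tested)
# this equals the trapezoid area under the ROC curve.
auroc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exhaustive PC-subset search under LOLOCV
#'
#' Evaluates the lesion-level AUROC of every candidate subset and returns the
#' maximizer. Ties (AUROC within 1e-12 of the maximum) are broken by smallest
#' subset size, then lexicographically.
#'
#' @param fs A [lolo_fold_scores()] cache.
#' @param subsets List of integer PC-index vectors, e.g. from
#'   [enumerate_pc_subsets()].
#' @param reg Ridge penalty.
#' @param lesion_labels Optional label override (see [lolo_cv_predict()]).
#' @return A `model_search_result`: `auroc` (vector, one per subset),
#'   `subsets`, `best_subset`, `best_auroc`, `ties` (list of tied subsets),
#'   `n_nonconverged`.
#' @export
search_best_subset <- function(fs, subsets, reg = 1e-4, lesion_labels = NULL) {
  if (length(subsets) == 0L) stop_rs("empty subset list", class = "config_error")
  lesion_labels <- lesion_labels %||% fs$lesion_labels
  res <- run_subset_search_cpp(fs, subsets, reg, lesion_labels)
  y <- as_binary_labels(lesion_labels)
  P <- lesion_posterior_matrix(res, length(fs$folds))
  auc <- apply(P, 1L, auroc_rank, y = y)
  best_auc <- max(auc)
  tie_idx <- which(auc >= best_auc - 1e-12)
  ord <- order(lengths(subsets[tie_idx]),
               vapply(subsets[tie_idx], function(s)
                 paste(sprintf("%03d", s), collapse = ""), ""))
  tie_idx <- tie_idx[ord]
  structure(list(auroc = auc, subsets = subsets,
                 best_subset = subsets[[tie_idx[1]]],
                 best_auroc = auc[tie_idx[1]],
                 ties = subsets[tie_idx],
                 n_nonconverged = res$n_nonconverged),
            class = "model_search_result")
}

#' @export
print.model_search_result <- function(x, ...) {
  cat(sprintf("<model_search_result: %d subsets, best AUROC %.4f with PCs {%s}%s>\n",
              length(x$subsets), x$best_auroc,
              paste(x$best_subset, collapse = ","),
              if (length(x$ties) > 1L)
                sprintf(", %d tied subsets", length(x$ties)) else ""))
  invisible(x)
}
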