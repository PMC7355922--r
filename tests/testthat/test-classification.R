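test_that("PCA of two symmetric points is their difference direction with fraction 1", {
  a <- c(1, 2, 3, 4); b <- c(3, 2, 1, 0)
  m <- fit_pca(rbind(a, b), 1L)
  expect_equal(m$explained_variance_fraction, 1)
  dir <- (a - b) / sqrt(sum((a - b)^2))
  if (sum(dir * m$loadings[1, ]) < 0) dir <- -dir
  expect_equal(drop(m$loadings), dir, ignore_attr = TRUE)
})

test_that("PCA reconstruction with all components reproduces the data", {
  set.seed(2)
  X <- matrix(rnorm(20 * 12), 20, 12)
  m <- fit_pca(X, 12L)
  scores <- project(m, X)
  recon <- sweep(scores %*% m$loadings, 2L, m$mean, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  # loadings orthonormal, components ordered, sign convention
  G <- m$loadings %*% t(m$loadings)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  expect_true(all(diff(m$explained_variance_fraction) <= 1e-12))
  for (i in seq_len(nrow(m$loadings))) {
    expect_gt(m$loadings[i, which.max(abs(m$loadings[i, ]))], 0)
  }
})

test_that("PCA truncates and flags rank-deficient input", {
  X <- matrix(rnorm(8), 4, 2)
  X <- cbind(X, X[, 1] + X[, 2])        # rank 2 in 3 columns
  m <- fit_pca(X, 3L)
  expect_identical(m$n_components, 2L)
  expect_true(attr(m, "rank_deficient"))
  expect_error(fit_pca(X, 4L), class = "config_error")
})

test_that("projection uses the training rotation without refitting", {
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_pca(X, 4L)
  expect_equal(drop(project(m, m$mean)), rep(0, 4), ignore_attr = TRUE)
  expect_equal(project(m, X[7, ]), project(m, X)[7, , drop = FALSE],
               ignore_attr = TRUE)
  expect_error(project(m, matrix(0, 1, 9)), class = "shape_error")
})

test_that("PC-subset enumeration matches brute force and is deterministic", {
  expect_identical(enumerate_pc_subsets(1, 1), list(1L))
  expect_identical(enumerate_pc_subsets(3, 2),
                   list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_error(enumerate_pc_subsets(3, 4), class = "config_error")
  sizes <- lengths(enumerate_pc_subsets(8, 3))
  expect_true(all(diff(sizes) >= 0))   # ordered by size
})

test_that("logistic fit honours symmetry, regularization, and an independent optimizer", {
  # symmetric balanced data -> zero intercept
  Z <- matrix(c(-2, -1, 1, 2), ncol = 1)
  m <- fit_logistic(Z, c(0, 0, 1, 1), reg = 0.01)
  expect_lt(abs(m$intercept), 1e-6)

  # separable 1-D data: ridge keeps coefficients finite, probabilities monotone
  msep <- fit_logistic(Z, c(0, 0, 1, 1), reg = 1e-4)
  expect_true(is.finite(msep$coefficients))
  p <- predict(msep, matrix(seq(-3, 3, 0.5), ncol = 1))
  expect_true(all(diff(p) > 0))

  # 6-point fixture vs a derivative-free penalized-likelihood optimizer
  Z6 <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  y6 <- c(0, 0, 1, 0, 1, 1)
  reg <- 0.05
  m6 <- fit_logistic(Z6, y6, reg = reg)
  negpll <- function(b) {
    eta <- b[1] + Z6 %*% b[2]
    sum(log1p(exp(eta))) - sum(y6 * eta) + reg * b[2]^2
  }
  o <- optim(c(0, 0), negpll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 10000))
  expect_lt(max(abs(c(m6$intercept, m6$coefficients) - o$par)), 1e-4)

  expect_error(fit_logistic(Z6, rep(1, 6), reg), class = "fit_error")
})

test_that("unpenalized fits agree with glm on non-separable data", {
  set.seed(8)
  Z <- matrix(rnorm(60 * 2), 60, 2)
  y <- rbinom(60, 1, plogis(0.3 + Z %*% c(1, -0.5)))
  m <- fit_logistic(Z, y, reg = 0)
  g <- glm(y ~ Z, family = binomial())
  expect_equal(c(m$intercept, m$coefficients), unname(coef(g)),
               tolerance = 1e-6)
})

test_that("fold caching equals a from-scratch fit on every fold", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  expect_length(fs$folds, nrow(lesion_table(ds)))
  M <- spectra_matrix(ds)
  f <- fs$folds[[3]]
  pca <- fit_pca(M[f$train_idx, , drop = FALSE], 4L)
  expect_lt(max(abs(project(pca, M[f$train_idx, , drop = FALSE]) - f$train_scores)), 1e-10)
  expect_lt(max(abs(project(pca, M[f$test_idx, , drop = FALSE]) - f$test_scores)), 1e-10)
})

test_that("the held-out lesion never leaks into its fold's PCA or model", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  target <- fs$folds[[2]]$lesion_id
  ds2 <- ds
  for (id in names(ds2$spectra)) {
    if (ds2$spectra[[id]]$lesion_id == target) {
      y <- ds2$spectra[[id]]$intensities
      y <- y + 0.5 * mean(abs(y)) * sin(seq_along(y))
      ds2$spectra[[id]]$intensities <- y / ramanscreen:::trapz_area(
        ds2$spectra[[id]]$wavenumbers, y)
    }
  }
  fs2 <- lolo_fold_scores(ds2, 4L)
  expect_equal(fs2$folds[[2]]$train_scores, fs$folds[[2]]$train_scores,
               tolerance = 1e-12)
})

test_that("lesion posteriors are the max over measurement probabilities (OR rule)", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  cv <- lolo_cv_predict(fs, c(1L, 2L), 1e-4)
  expect_identical(cv$n_folds, length(fs$lesion_ids))
  for (les in fs$lesion_ids) {
    ids <- ds$measurements$measurement_id[ds$measurements$lesion_id == les]
    expect_identical(unname(cv$lesion_posterior[les]),
                     max(cv$spectrum_prob[ids]))
  }
})

test_that("swapping class labels reflects all probabilities", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  cv1 <- lolo_cv_predict(fs, c(1L, 3L), 1e-4)
  swapped <- ifelse(fs$lesion_labels == "melanoma", "pigmented", "melanoma")
  cv2 <- lolo_cv_predict(fs, c(1L, 3L), 1e-4, lesion_labels = swapped)
  expect_lt(max(abs(cv1$spectrum_prob - (1 - cv2$spectrum_prob))), 1e-8)
})

test_that("a strongly separated noiseless cohort is classified perfectly", {
  cfg <- clean_config(n_pig = 6L, n_mel = 3L, n_points = 250L,
                      weight_cv = 0.05, intra_lesion_cv = 0.02)
  pre <- preprocess_dataset(generate_cohort(cfg)$dataset)
  fs <- lolo_fold_scores(pre, 4L)
  sr <- search_best_subset(fs, enumerate_pc_subsets(4, 2), 1e-4)
  expect_identical(sr$best_auroc, 1)
  cv <- lolo_cv_predict(fs, sr$best_subset, 1e-4)
  lab <- setNames(fs$lesion_labels, fs$lesion_ids)
  expect_gt(min(cv$lesion_posterior[lab == "melanoma"]),
            max(cv$lesion_posterior[lab == "pigmented"]))
})

test_that("subset search agrees with the naive uncached pipeline", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 6L, n_mel = 4L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  subsets <- list(1L, c(1L, 2L), c(2L, 4L))
  sr <- search_best_subset(fs, subsets, 1e-4)
  lab <- ramanscreen:::as_binary_labels(fs$lesion_labels)
  naive_auc <- vapply(subsets, function(s) {
    np <- naive_lolo_predict(ds, s, 4L, 1e-4)
    roc_curve(np$lesion_posterior, setNames(fs$lesion_labels, fs$lesion_ids))$auroc
  }, 0)
  expect_equal(unname(sr$auroc), naive_auc, tolerance = 1e-10)
  expect_identical(sr$best_subset, subsets[[which.max(naive_auc)]])
  # duplicated subset: identical AUROC (determinism)
  sr2 <- search_best_subset(fs, c(subsets, subsets[2]), 1e-4)
  expect_identical(sr2$auroc[2], sr2$auroc[4])
  # single-subset search returns that subset
  expect_identical(search_best_subset(fs, list(c(2L, 3L)), 1e-4)$best_subset,
                   c(2L, 3L))
})

test_that("subset AUROCs are invariant to measurement order within lesions", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  set.seed(4)
  perm <- unlist(lapply(split(seq_along(ds$spectra), ds$measurements$lesion_id),
                        sample), use.names = FALSE)
  ds_p <- spectra_dataset(ds$spectra[perm], ds$lesions,
                          measurements = ds$measurements[perm, ])
  subsets <- enumerate_pc_subsets(4, 2)
  a1 <- search_best_subset(lolo_fold_scores(ds, 4L), subsets, 1e-4)$auroc
  a2 <- search_best_subset(lolo_fold_scores(ds_p, 4L), subsets, 1e-4)$auroc
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("ties break to the smallest, lexicographically first subset", {
  ds <- preprocess_dataset(tiny_cohort(n_pig = 5L, n_mel = 3L, n_points = 200L))
  fs <- lolo_fold_scores(ds, 4L)
  sr <- search_best_subset(fs, enumerate_pc_subsets(4, 3), 1e-4)
  expect_true(all(vapply(sr$ties, function(s)
    abs(sr$best_auroc - sr$auroc[[which(vapply(sr$subsets, identical, TRUE, s))]]) <= 1e-12,
    TRUE)))
  tie_sizes <- lengths(sr$ties)
  expect_identical(length(sr$best_subset), min(tie_sizes))
})
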