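# Shared fixtures: small synthetic configurations keep unit tests fast while
# exercising the same code paths as the full-size cohort.

tiny_config <- function(n_pig = 8L, n_mel = 4L, n_points = 300L, seed = 3L, ...) {
  synthetic_config(n_pigmented_lesions = n_pig, n_melanoma_lesions = n_mel,
                   n_patients = n_pig + n_mel,
                   grid = list(min = 800, max = 1790, n_points = n_points),
                   seed = seed, ...)
}

tiny_cohort <- function(...) generate_cohort(tiny_config(...))$dataset

# Clean (artifact-free, deterministic-per-lesion) configuration: pure
# constituent mixtures, no baseline / noise / spikes / jitter.
clean_config <- function(..., weight_cv = 0, intra_lesion_cv = 0) {
  cfg <- tiny_config(...)
  cfg$noise_sd <- 0
  cfg$cosmic_ray_rate <- 0
  cfg$weight_cv <- weight_cv
  cfg$intra_lesion_cv <- intra_lesion_cv
  cfg$baseline_coeff_ranges[] <- 0
  cfg
}

# Toy lesion posterior set mirroring the screening study's confusion table:
# 7 melanomas at 0.9, 22 pigmented above them at 0.95, 31 pigmented at 0.1.
table1_posteriors <- function() {
  post <- c(rep(0.9, 7), rep(0.95, 22), rep(0.1, 31))
  labels <- c(rep("melanoma", 7), rep("pigmented", 53))
  names(post) <- names(labels) <- sprintf("L%02d", seq_along(post))
  list(posteriors = post, labels = labels)
}

# Independent naive LOLOCV: refits PCA and the logistic model from scratch
# for every fold, no caching. Mirrors the pipeline's contract (training-SD
# standardization of scores before the logistic stage). Oracle for the
# cached pipeline.
naive_lolo_predict <- function(ds, subset, n_pcs, reg) {
  M <- spectra_matrix(ds)
  lt <- lesion_table(ds)
  mlab <- measurement_labels(ds)
  probs <- numeric(0)
  for (les in lt$lesion_id) {
    te <- which(ds$measurements$lesion_id == les)
    tr <- setdiff(seq_len(nrow(M)), te)
    pca <- fit_pca(M[tr, , drop = FALSE], n_pcs)
    Str <- project(pca, M[tr, , drop = FALSE])
    Ste <- project(pca, M[te, , drop = FALSE])
    sds <- apply(Str, 2L, sd)
    Ztr <- sweep(Str, 2L, sds, `/`)[, subset, drop = FALSE]
    Zte <- sweep(Ste, 2L, sds, `/`)[, subset, drop = FALSE]
    m <- fit_logistic(Ztr, mlab[tr], reg)
    p <- predict(m, Zte)
    names(p) <- ds$measurements$measurement_id[te]
    probs <- c(probs, p)
  }
  posterior <- tapply(probs, ds$measurements$lesion_id[
    match(names(probs), ds$measurements$measurement_id)], max)
  list(spectrum_prob = probs,
       lesion_posterior = posterior[lt$lesion_id])
}

# Brute-force AUROC: concordant melanoma/pigmented pairs plus half ties.
pairwise_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
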