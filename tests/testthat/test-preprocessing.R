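make_spec <- function(y, grid = seq_along(y)) spectrum_record("m1", "l1", grid, y)

test_that("dark subtraction is exact elementwise arithmetic", {
  set.seed(1)
  y <- runif(50); dark <- runif(50)
  out <- subtract_dark(make_spec(y), dark)
  expect_equal(out$intensities, y - dark, tolerance = 1e-15)
  expect_equal(subtract_dark(make_spec(y), rep(0, 50))$intensities, y)
  expect_equal(subtract_dark(make_spec(y), y)$intensities, rep(0, 50))
  expect_error(subtract_dark(make_spec(y), rep(0, 49)), class = "shape_error")
})

test_that("cosmic-ray removal flags planted spikes and leaves clean spectra alone", {
  grid <- seq(800, 1790, length.out = 400)
  clean <- 100 + 50 * exp(-0.5 * ((grid - 1200) / 30)^2) + 5 * sin(grid / 40)
  expect_equal(remove_cosmic_rays(make_spec(clean, grid))$intensities, clean)

  spiked <- clean
  pos <- c(120, 290)
  spiked[pos] <- spiked[pos] + 10 * max(clean)
  out <- remove_cosmic_rays(make_spec(spiked, grid))
  expect_identical(attr(out, "n_flagged"), 2L)
  expect_false(attr(out, "cosmic_warning"))
  rel <- abs(out$intensities[pos] - clean[pos]) / clean[pos]
  expect_lt(max(rel), 0.01)
})

test_that("a spike at the first grid point is repaired by nearest-neighbour extension", {
  y <- rep(10, 100) + sin(seq_len(100) / 5)
  y[1] <- y[1] + 500
  out <- remove_cosmic_rays(make_spec(y))
  expect_gte(attr(out, "n_flagged"), 1L)
  expect_lt(abs(out$intensities[1] - out$intensities[2]), 1)
})

test_that("mass flagging aborts the repair with a warning flag", {
  # 8% of points spiked: far beyond any plausible cosmic-ray density, so the
  # spectrum is returned untouched with a warning
  set.seed(1)
  y <- 100 + 10 * sin(seq_len(400) / 15) + rnorm(400)
  pos <- sample(400, 32)
  y[pos] <- y[pos] + 20 * max(y)
  out <- remove_cosmic_rays(make_spec(y))
  expect_true(attr(out, "cosmic_warning"))
  expect_identical(attr(out, "n_flagged"), 0L)
  expect_equal(out$intensities, y)
})

test_that("Savitzky-Golay smoothing is exact on low-degree polynomials and contracts noise", {
  x <- seq(0, 1, length.out = 151)
  y <- 2 - 3 * x + 0.5 * x^2 + x^3   # degree 3 = default polyorder
  out <- smooth_spectrum(make_spec(y, seq_along(x)))
  expect_lt(max(abs(out$intensities - y)), 1e-8)

  set.seed(7)
  ratios <- replicate(100, {
    noise <- rnorm(200)
    var(smooth_spectrum(make_spec(noise))$intensities) / var(noise)
  })
  expect_true(all(ratios < 1))

  cfg1 <- preprocess_config(smooth_window = 1L)
  expect_equal(smooth_spectrum(make_spec(y), cfg1)$intensities, y)
  expect_error(smooth_spectrum(make_spec(1:5), preprocess_config()),
               class = "config_error")
})

test_that("modpoly baseline is a fixed point on pure polynomials and zero on zero", {
  grid <- seq(800, 1790, length.out = 500)
  t <- 2 * (grid - 800) / 990 - 1
  poly5 <- 1000 + 200 * t - 150 * t^2 + 40 * t^3 - 25 * t^4 + 10 * t^5
  bl <- modpoly_baseline(make_spec(poly5, grid))
  expect_lt(max(abs(as.numeric(bl) - poly5) / abs(poly5)), 1e-6)
  expect_true(attr(bl, "converged"))

  bl0 <- modpoly_baseline(make_spec(rep(0, 500), grid))
  expect_equal(as.numeric(bl0), rep(0, 500))
})

test_that("modpoly recovers a generator baseline under peaks to within 2% RMS", {
  cfg <- tiny_config(n_points = 600L)
  cfg$noise_sd <- 0; cfg$cosmic_ray_rate <- 0
  w <- cfg$class_weight_means["pigmented", ]
  errs <- vapply(1:10, function(i) {
    set.seed(100 + i)
    r <- render_raw_measurement(w, 0, cfg)
    bl <- modpoly_baseline(r$record)
    sqrt(mean((as.numeric(bl) - r$truth$baseline)^2)) /
      sqrt(mean(r$truth$baseline^2))
  }, 0)
  expect_lt(max(errs), 0.02)
})

test_that("intensity-response correction is mean-normalized and scale-invariant", {
  set.seed(3)
  y <- runif(80, 1, 2)
  flat <- rep(4, 80)
  expect_equal(correct_intensity_response(make_spec(y), flat)$intensities, y)
  expect_equal(correct_intensity_response(make_spec(y), 2 * flat)$intensities, y)
  ramp <- seq(0.5, 1.5, length.out = 80)
  out <- correct_intensity_response(make_spec(y), ramp)
  expect_equal(out$intensities, y / (ramp / mean(ramp)), tolerance = 1e-12)
  expect_error(correct_intensity_response(make_spec(y), c(-1, ramp[-1])),
               class = "calibration_error")
})

test_that("cropping is inclusive and exact", {
  grid <- seq(800, 1790, length.out = 1980)
  spec <- make_spec(rep(1, 1980), grid)
  expect_length(crop_spectrum(spec, 800, 1790)$wavenumbers, 1980L)

  g2 <- seq(900, 1100, by = 0.5)
  out <- crop_spectrum(make_spec(rep(1, length(g2)), g2), 1000, 1001)
  expect_length(out$wavenumbers, 3L)
  expect_error(crop_spectrum(make_spec(rep(1, length(g2)), g2), 1000, 1000.2),
               class = "range_error")
})

test_that("area normalization has the closed form and is idempotent", {
  grid <- seq(0, 10, length.out = 101)      # span L = 10
  out <- normalize_area(make_spec(rep(3, 101), grid))
  expect_equal(out$intensities, rep(1 / 10, 101), tolerance = 1e-12)
  expect_identical(out$stage, "preprocessed")
  out2 <- normalize_area(out)
  expect_equal(out2$intensities, out$intensities, tolerance = 1e-12)

  set.seed(9)
  r <- normalize_area(make_spec(runif(200, 0.1, 2), seq(800, 999, length.out = 200)))
  expect_lt(abs(ramanscreen:::trapz_area(r$wavenumbers, r$intensities) - 1), 1e-9)
  expect_error(normalize_area(make_spec(rep(0, 50))),
               class = "normalization_error")
})

test_that("preprocess_dataset yields unit-area fingerprint spectra with QC flags", {
  ds <- tiny_cohort(n_pig = 4L, n_mel = 2L, n_points = 900L)
  pre <- preprocess_dataset(ds)
  expect_true(all(vapply(pre$spectra, `[[`, "", "stage") == "preprocessed"))
  expect_length(validate_dataset(pre), 0L)
  qc <- attr(pre, "qc")
  expect_setequal(qc$measurement_id, names(pre$spectra))
  expect_true(all(qc$baseline_converged))
  # input untouched
  expect_true(all(vapply(ds$spectra, `[[`, "", "stage") == "raw"))
  expect_error(preprocess_dataset(pre), class = "precondition_error")
})

mixture_rms <- function(cfg) {
  gen <- generate_cohort(cfg)
  pre <- preprocess_dataset(gen$dataset)
  grid <- pre$spectra[[1]]$wavenumbers
  vapply(names(pre$spectra), function(id) {
    pure <- gen$truth$measurements[[id]]$signal
    pure_n <- pure / ramanscreen:::trapz_area(grid, pure)
    sqrt(mean((pre$spectra[[id]]$intensities - pure_n)^2)) /
      sqrt(mean(pure_n^2))
  }, 0)
}

test_that("an artifact-free noiseless narrow-band cohort preprocesses to the pure mixtures", {
  # narrow-band constituents only: the polynomial baseline has nothing to
  # confuse with signal, so the mixtures pass through nearly unchanged
  cfg <- clean_config(n_pig = 3L, n_mel = 2L, n_points = 1980L)
  cfg$class_weight_means[, "melanin"] <- 0
  cfg$class_weight_means[, "water"] <- 0
  expect_lt(max(mixture_rms(cfg)), 0.02)
})

test_that("broad melanin/water bands are only moderately attenuated by baseline removal", {
  # an order-5 baseline fit inevitably absorbs part of ~100 cm^-1-wide bands;
  # with the default broad-band weights the distortion stays bounded
  cfg <- clean_config(n_pig = 3L, n_mel = 2L, n_points = 1980L)
  expect_lt(max(mixture_rms(cfg)), 0.12)
})

test_that("baseline subtraction does not inflate the reference signal peak", {
  cfg <- tiny_config(n_points = 1100L)
  cfg$cosmic_ray_rate <- 0
  gen <- generate_cohort(cfg)
  for (id in names(gen$dataset$spectra)[1:6]) {
    truth <- gen$truth$measurements[[id]]
    j <- which.max(truth$signal)
    # compare on the unnormalized scale: signal + (baseline - fit) at the peak
    sm <- smooth_spectrum(remove_cosmic_rays(gen$dataset$spectra[[id]]))
    corrected <- sm$intensities[j] - as.numeric(modpoly_baseline(sm))[j]
    tol <- 3 * cfg$noise_sd + 0.02 * truth$signal[j]
    expect_lt(corrected - truth$signal[j], tol)
  }
})

test_that("the full chain is invariant to positive rescaling of raw spectra", {
  ds <- tiny_cohort(n_pig = 3L, n_mel = 2L, n_points = 250L)
  ds2 <- ds
  for (i in seq_along(ds2$spectra)) {
    ds2$spectra[[i]]$intensities <- 3.7 * ds2$spectra[[i]]$intensities
  }
  expect_equal(spectra_matrix(preprocess_dataset(ds2)),
               spectra_matrix(preprocess_dataset(ds)), tolerance = 1e-8)
})

test_that("preprocessing is per-spectrum: permuting the dataset permutes outputs", {
  ds <- tiny_cohort(n_pig = 3L, n_mel = 2L, n_points = 200L)
  perm <- rev(seq_along(ds$spectra))
  ds_p <- spectra_dataset(ds$spectra[perm], ds$lesions,
                          measurements = ds$measurements[perm, ])
  M1 <- spectra_matrix(preprocess_dataset(ds))
  M2 <- spectra_matrix(preprocess_dataset(ds_p))
  expect_equal(M2[, ], M1[rownames(M2), ], tolerance = 1e-12,
               ignore_attr = "wavenumbers")
})
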