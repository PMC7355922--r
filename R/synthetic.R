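# Synthetic Raman cohort generator. Spectra are hierarchical mixtures of
# tissue-constituent basis spectra (lesion-level mixing weights, measurement-
# level jitter) plus the artifacts the preprocessing chain is built to remove:
# a slowly varying order-5 polynomial fluorescence baseline, additive Gaussian
# noise, and single-pixel cosmic-ray spikes.

#' Default tissue-constituent basis peak tables
#'
#' Eight constituents commonly resolved in skin Raman spectra, each described
#' by Gaussian peaks (center cm^-1, sigma cm^-1, relative amplitude) placed at
#' standard band assignments: CH2/CH3 deformation ~1440-1450 for lipids,
#' Amide III ~1250-1270 and proline/hydroxyproline 855/940 for collagen,
#' phenylalanine 1003 for keratin, broad melanin 1380/1580 doublet, OH bend
#' ~1640 for water.
#'
#' @return Named list; each element is a data frame with columns `center`,
#'   `sigma`, `amplitude`.
#' @export
default_constituent_bases <- function() {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], sigma = m[, 2], amplitude = m[, 3])
  }
  list(
    collagen = pk(855, 10, 0.7,   940, 10, 0.6,  1248, 14, 0.8,
                  1271, 12, 0.6,  1450, 14, 0.5, 1660, 16, 1.0),
    triolein = pk(1078, 12, 0.5,  1267, 10, 0.6, 1301, 10, 0.8,
                  1440, 12, 1.0,  1655, 10, 0.5, 1747, 10, 0.4),
    ceramide = pk(1063, 10, 0.6,  1130, 10, 0.5, 1296, 10, 0.7,
                  1441, 12, 1.0,  1650, 14, 0.4),
    keratin  = pk(1004,  6, 0.8,  1209, 10, 0.3, 1250, 14, 0.6,
                  1340, 12, 0.5,  1450, 14, 0.9, 1655, 14, 1.0),
    elastin  = pk(1104, 12, 0.4,  1254, 14, 0.6, 1339, 12, 0.5,
                  1450, 14, 0.9,  1660, 16, 1.0),
    melanin  = pk(1380, 50, 1.0,  1580, 50, 0.9),
    dna      = pk(1094, 12, 0.7,  1320, 12, 0.5, 1485, 12, 0.6, 1578, 10, 0.8),
    water    = pk(1640, 60, 1.0)
  )
}

#' Default per-class mean constituent mixing weights
#'
#' Encodes the discriminating structure the classifier is meant to find:
#' melanoma has more collagen and DNA, less triolein (reduced CH2/CH3 lipid
#' bands) than pigmented lesions.
#'
#' @return 2 x 8 matrix, rows `pigmented` / `melanoma`, columns constituents.
#' @export
default_class_weight_means <- function() {
  m <- rbind(
    pigmented = c(collagen = 0.30, triolein = 0.20, ceramide = 0.08,
                  keratin = 0.18, elastin = 0.06, melanin = 0.08,
                  dna = 0.04, water = 0.06),
    melanoma  = c(collagen = 0.38, triolein = 0.10, ceramide = 0.06,
                  keratin = 0.16, elastin = 0.05, melanin = 0.12,
                  dna = 0.08, water = 0.05))
  m
}

#' Default fluorescence-baseline coefficient ranges
#'
#' Coefficient ranges (counts) for an order-5 polynomial in the wavenumber
#' coordinate rescaled to \[-1, 1\]; the constant term dominates so the
#' baseline is large and slowly varying relative to the Raman peaks, as in
#' tissue spectra.
#'
#' @return 6 x 2 matrix of (lo, hi) per polynomial order 0..5.
#' @export
default_baseline_ranges <- function() {
  m <- matrix(c(600, 1500,
                -400, 0,
                -150, 150,
                -80, 80,
                -60, 60,
                -40, 40), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("c", 0:5), c("lo", "hi")))
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort: 52 patients, 53 pigmented lesions
#' (about 158 measurements) and 7 melanoma lesions (about 27 measurements) on
#' a 1980-point grid over 800-1790 cm^-1, with class structure carried by
#' collagen/triolein weights and a +10 cm^-1 Amide III shift for melanoma.
#'
#' @param n_pigmented_lesions,n_melanoma_lesions,n_patients Cohort counts.
#' @param measurements_per_lesion Integer range (lo, hi) of measurements per
#'   lesion.
#' @param measurement_count_probs Per-class probabilities over that range,
#'   chosen so expected totals match 158 pigmented / 27 melanoma measurements.
#' @param grid List `min`, `max` (cm^-1), `n_points`.
#' @param constituents Basis peak tables, see [default_constituent_bases()].
#' @param class_weight_means Per-class mean mixing weights,
#'   see [default_class_weight_means()].
#' @param weight_cv Relative dispersion of lesion-level weights.
#' @param intra_lesion_cv Relative dispersion across measurements in a lesion.
#' @param amideIII_shift cm^-1 shift of collagen Amide III peaks (1230-1300)
#'   for melanoma lesions.
#' @param signal_scale Overall Raman signal amplitude (counts x cm^-1; the
#'   unit-area mixture is multiplied by this).
#' @param baseline_coeff_ranges See [default_baseline_ranges()].
#' @param noise_sd Additive Gaussian noise sd (counts).
#' @param cosmic_ray_rate Expected cosmic spikes per spectrum.
#' @param cosmic_ray_amplitude Spike amplitude range, as multiples of the
#'   spike-free spectrum maximum.
#' @param seed Root seed for the cohort RNG stream.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_pigmented_lesions = 53L,
                             n_melanoma_lesions = 7L,
                             n_patients = 52L,
                             measurements_per_lesion = c(2L, 6L),
                             measurement_count_probs = list(
                               pigmented = c(0.45, 0.30, 0.13, 0.08, 0.04),
                               melanoma = c(0.15, 0.25, 0.30, 0.20, 0.10)),
                             grid = list(min = 800, max = 1790, n_points = 1980L),
                             constituents = default_constituent_bases(),
                             class_weight_means = default_class_weight_means(),
                             weight_cv = 0.25,
                             intra_lesion_cv = 0.10,
                             amideIII_shift = 10,
                             signal_scale = 5e4,
                             baseline_coeff_ranges = default_baseline_ranges(),
                             noise_sd = 4,
                             cosmic_ray_rate = 0.3,
                             cosmic_ray_amplitude = c(5, 20),
                             seed = 0L) {
  cfg <- list(n_pigmented_lesions = as.integer(n_pigmented_lesions),
              n_melanoma_lesions = as.integer(n_melanoma_lesions),
              n_patients = as.integer(n_patients),
              measurements_per_lesion = as.integer(measurements_per_lesion),
              measurement_count_probs = measurement_count_probs,
              grid = grid, constituents = constituents,
              class_weight_means = class_weight_means,
              weight_cv = weight_cv, intra_lesion_cv = intra_lesion_cv,
              amideIII_shift = amideIII_shift, signal_scale = signal_scale,
              baseline_coeff_ranges = baseline_coeff_ranges,
              noise_sd = noise_sd, cosmic_ray_rate = cosmic_ray_rate,
              cosmic_ray_amplitude = cosmic_ray_amplitude,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_pigmented_lesions < 0L || cfg$n_melanoma_lesions < 0L ||
      cfg$n_patients <= 0L) {
    stop_rs("cohort counts must be positive", class = "config_error")
  }
  if (any(cfg$class_weight_means < 0)) {
    stop_rs("class weight means must be non-negative", class = "config_error")
  }
  # Direction of the planted lipid effect; equality admitted so a null
  # configuration (identical class means) is representable.
  if (cfg$class_weight_means["melanoma", "triolein"] >
      cfg$class_weight_means["pigmented", "triolein"]) {
    stop_rs("melanoma mean triolein weight must not exceed the pigmented mean",
            class = "config_error")
  }
  nles <- cfg$n_pigmented_lesions + cfg$n_melanoma_lesions
  if (nles > 2L * cfg$n_patients) {
    stop_rs("%d lesions cannot be assigned to %d patients (max 2 per patient)",
            nles, cfg$n_patients, class = "config_error")
  }
  centers <- unlist(lapply(cfg$constituents, `[[`, "center"))
  if (any(centers < 700 | centers > 1900)) {
    stop_rs("constituent peak centers must lie in [700, 1900] cm^-1",
            class = "config_error")
  }
  invisible(cfg)
}

#' Null (no-effect) variant of a synthetic configuration
#'
#' Both classes share the pigmented mean weights and there is no Amide III
#' shift, so labels are independent of spectra by construction.
#'
#' @param cfg A `synthetic_config`.
#' @return Modified `synthetic_config`.
#' @export
null_synthetic_config <- function(cfg = synthetic_config()) {
  cfg$class_weight_means["melanoma", ] <- cfg$class_weight_means["pigmented", ]
  cfg$amideIII_shift <- 0
  cfg
}

cohort_grid <- function(cfg) {
  seq(cfg$grid$min, cfg$grid$max, length.out = cfg$grid$n_points)
}

#' Render constituent basis spectra on a grid
#'
#' Each basis row is the sum of its Gaussian peaks, clipped at zero and
#' normalized to unit trapezoid area.
#'
#' @param grid Strictly increasing wavenumber vector.
#' @param bases Named list of peak tables (see
#'   [default_constituent_bases()]).
#' @param amideIII_shift cm^-1 added to collagen peak centers in
#'   \[1230, 1300\] (melanoma variant); default 0.
#' @return Matrix, constituents x wavenumbers.
#' @export
build_constituent_bases <- function(grid, bases, amideIII_shift = 0) {
  stopifnot(all(diff(grid) > 0))
  B <- matrix(0, nrow = length(bases), ncol = length(grid),
              dimnames = list(names(bases), NULL))
  for (i in seq_along(bases)) {
    pk <- bases[[i]]
    if (is.null(pk) || nrow(pk) == 0L) {
      stop_rs("constituent '%s' has an empty peak list", names(bases)[i],
              class = "config_error")
    }
    centers <- pk$center
    if (names(bases)[i] == "collagen" && amideIII_shift != 0) {
      amide <- centers >= 1230 & centers <= 1300
      centers[amide] <- centers[amide] + amideIII_shift
    }
    row <- rep(0, length(grid))
    for (j in seq_len(nrow(pk))) {
      row <- row + pk$amplitude[j] *
        exp(-0.5 * ((grid - centers[j]) / pk$sigma[j])^2)
    }
    row <- pmax(row, 0)
    B[i, ] <- row / trapz_area(grid, row)
  }
  B
}

#' Draw one lesion's identity and constituent weights
#'
#' Lesion-level weights are Gaussian around the class means with relative
#' dispersion `weight_cv`, truncated at zero; the measurement count is drawn
#' from the per-class distribution. Uses the current RNG state.
#'
#' @param label `"melanoma"` or `"pigmented"`.
#' @param cfg A `synthetic_config`.
#' @return List with `weights` (named vector), `n_measurements`, `shift`.
#' @export
sample_lesion <- function(label, cfg) {
  label <- match.arg(label, VALID_LABELS)
  mu <- cfg$class_weight_means[label, ]
  w <- pmax(0, mu * (1 + cfg$weight_cv * rnorm(length(mu))))
  names(w) <- colnames(cfg$class_weight_means)
  rng <- cfg$measurements_per_lesion
  sizes <- seq(rng[1], rng[2])
  probs <- cfg$measurement_count_probs[[label]]
  stopifnot(length(probs) == length(sizes))
  n_meas <- sample(sizes, 1L, prob = probs)
  list(weights = w, n_measurements = n_meas,
       shift = if (label == "melanoma") cfg$amideIII_shift else 0)
}

draw_baseline <- function(grid, ranges) {
  coef <- runif(nrow(ranges), ranges[, "lo"], ranges[, "hi"])
  t <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  base <- drop(outer(t, seq_len(length(coef)) - 1, `^`) %*% coef)
  if (min(base) < 0) {            # keep fluorescence non-negative
    coef[1] <- coef[1] - min(base)
    base <- base - min(base)
  }
  list(baseline = base, coefficients = coef)
}

#' Render one raw synthetic measurement
#'
#' Intensities are the weighted constituent mixture (weights jittered by
#' `intra_lesion_cv`), scaled by `signal_scale`, plus an order-5 polynomial
#' fluorescence baseline, i.i.d. Gaussian noise, and Poisson-count
#' single-pixel cosmic spikes. Uses the current RNG state.
#'
#' @param weights Lesion-level constituent weights (named, non-negative).
#' @param shift Amide III shift (cm^-1) for this lesion.
#' @param cfg A `synthetic_config`.
#' @param measurement_id,lesion_id Identifiers for the record.
#' @param bases Optional precomputed basis matrix for this shift (speeds up
#'   cohort generation); built from `cfg` when `NULL`.
#' @return List: `record` (a raw [spectrum_record()]) and `truth`
#'   (measurement weights, baseline coefficients, spike positions).
#' @export
render_raw_measurement <- function(weights, shift, cfg,
                                   measurement_id = "m1", lesion_id = "l1",
                                   bases = NULL) {
  stopifnot(all(weights >= 0))
  grid <- cohort_grid(cfg)
  if (is.null(bases)) {
    bases <- build_constituent_bases(grid, cfg$constituents, shift)
  }
  w_m <- pmax(0, weights * (1 + cfg$intra_lesion_cv * rnorm(length(weights))))
  signal <- drop(w_m %*% bases) * cfg$signal_scale
  bl <- draw_baseline(grid, cfg$baseline_coeff_ranges)
  y <- signal + bl$baseline +
    if (cfg$noise_sd > 0) rnorm(length(grid), 0, cfg$noise_sd) else 0
  n_spikes <- rpois(1L, cfg$cosmic_ray_rate)
  spike_pos <- integer(0)
  if (n_spikes > 0) {
    spike_pos <- sample.int(length(grid), min(n_spikes, length(grid)))
    amp <- runif(length(spike_pos), cfg$cosmic_ray_amplitude[1],
                 cfg$cosmic_ray_amplitude[2]) * max(y)
    y[spike_pos] <- y[spike_pos] + amp
  }
  list(record = spectrum_record(measurement_id, lesion_id, grid, y, "raw"),
       truth = list(weights = w_m, baseline_coefficients = bl$coefficients,
                    baseline = bl$baseline, spike_positions = sort(spike_pos),
                    signal = signal))
}

#' Generate a full synthetic cohort
#'
#' Lesions are assigned to patients round-robin (so a few patients carry two
#' lesions, reconciling 60 lesions over 52 patients). Each lesion gets its own
#' RNG sub-stream derived from `cfg$seed`, so regeneration is stable.
#'
#' @param cfg A `synthetic_config`.
#' @return List: `dataset` (a valid raw [spectra_dataset()]) and `truth`
#'   (per-lesion weights and labels, per-measurement ground truth).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  validate_synthetic_config(cfg)
  grid <- cohort_grid(cfg)
  bases0 <- build_constituent_bases(grid, cfg$constituents, 0)
  bases_shift <- if (cfg$amideIII_shift != 0) {
    build_constituent_bases(grid, cfg$constituents, cfg$amideIII_shift)
  } else bases0

  n_total <- cfg$n_pigmented_lesions + cfg$n_melanoma_lesions
  labels <- c(rep("pigmented", cfg$n_pigmented_lesions),
              rep("melanoma", cfg$n_melanoma_lesions))
  lesion_ids <- sprintf("L%03d", seq_len(n_total))
  patient_ids <- sprintf("P%03d", ((seq_len(n_total) - 1L) %% cfg$n_patients) + 1L)

  spectra <- list()
  lesion_truth <- list()
  meas_truth <- list()
  for (i in seq_len(n_total)) {
    set.seed(child_seed(cfg$seed, i, stream = 1L))
    les <- sample_lesion(labels[i], cfg)
    lesion_truth[[lesion_ids[i]]] <- list(label = labels[i],
                                          weights = les$weights,
                                          n_measurements = les$n_measurements)
    B <- if (labels[i] == "melanoma") bases_shift else bases0
    for (k in seq_len(les$n_measurements)) {
      mid <- sprintf("%s_m%02d", lesion_ids[i], k)
      r <- render_raw_measurement(les$weights, les$shift, cfg,
                                  measurement_id = mid,
                                  lesion_id = lesion_ids[i], bases = B)
      spectra[[mid]] <- r$record
      meas_truth[[mid]] <- r$truth
    }
  }
  lesions <- data.frame(lesion_id = lesion_ids, patient_id = patient_ids,
                        label = labels, stringsAsFactors = FALSE)
  ds <- spectra_dataset(spectra, lesions)
  v <- validate_dataset(ds)
  if (length(v)) {
    stop_rs("generated cohort failed validation: %s", paste(v, collapse = "; "),
            class = "internal_error")
  }
  list(dataset = ds,
       truth = list(lesions = lesion_truth, measurements = meas_truth,
                    seed = cfg$seed))
}
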