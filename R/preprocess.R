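# Preprocessing chain: raw counts -> unit-area fingerprint spectra.
# Order: dark subtraction, cosmic-ray removal, Savitzky-Golay smoothing,
# iterative modified-polynomial (order 5) fluorescence-baseline subtraction,
# intensity-response correction, crop to 800-1790 cm^-1, area normalization.

#' Preprocessing configuration
#'
#' @param dark_spectrum Optional dark-count vector (same grid as the data).
#' @param cosmic_window Odd running-median window for spike detection.
#' @param cosmic_k MAD multiplier above which a point is flagged as a spike.
#' @param smooth_window Odd Savitzky-Golay window length (1 disables).
#' @param smooth_polyorder Savitzky-Golay polynomial order.
#' @param baseline_order Fluorescence-polynomial order.
#' @param baseline_max_iter,baseline_tol Modified-polyfit stopping rule:
#'   stop when the maximum relative change of the fitted baseline drops below
#'   `baseline_tol`, or after `baseline_max_iter` iterations.
#' @param response_curve Optional relative intensity-response vector (> 0).
#' @param crop Inclusive wavenumber window retained, cm^-1.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(dark_spectrum = NULL,
                              cosmic_window = 5L, cosmic_k = 8,
                              smooth_window = 11L, smooth_polyorder = 3L,
                              baseline_order = 5L, baseline_max_iter = 100L,
                              baseline_tol = 1e-4,
                              response_curve = NULL,
                              crop = c(800, 1790)) {
  if (smooth_window > 1L && smooth_polyorder >= smooth_window) {
    stop_rs("smooth_polyorder must be < smooth_window", class = "config_error")
  }
  if (cosmic_window %% 2L == 0L || (smooth_window > 1L && smooth_window %% 2L == 0L)) {
    stop_rs("cosmic_window and smooth_window must be odd", class = "config_error")
  }
  if (baseline_order < 1L) stop_rs("baseline_order must be >= 1", class = "config_error")
  if (crop[1] >= crop[2]) stop_rs("crop min must be < crop max", class = "config_error")
  structure(list(dark_spectrum = dark_spectrum,
                 cosmic_window = as.integer(cosmic_window), cosmic_k = cosmic_k,
                 smooth_window = as.integer(smooth_window),
                 smooth_polyorder = as.integer(smooth_polyorder),
                 baseline_order = as.integer(baseline_order),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 response_curve = response_curve, crop = crop),
            class = "preprocess_config")
}

#' Subtract a dark-count spectrum
#'
#' Elementwise subtraction; negatives are permitted (later stages tolerate
#' them).
#'
#' @param spec A [spectrum_record()].
#' @param dark Numeric vector, same length as the spectrum.
#' @return The corrected `spectrum_record`.
#' @export
subtract_dark <- function(spec, dark) {
  if (length(dark) != length(spec$intensities)) {
    stop_rs("spectrum '%s': dark spectrum length %d != %d",
            spec$measurement_id, length(dark), length(spec$intensities),
            class = "shape_error")
  }
  spec$intensities <- spec$intensities - dark
  spec
}

#' Remove cosmic-ray spikes
#'
#' Points deviating from a running median by more than `cosmic_k` times the
#' MAD of the residuals are replaced by linear interpolation of the nearest
#' non-flagged neighbours (nearest-neighbour extension at the edges). If more
#' than 5\% of points would be flagged the spectrum is returned unchanged with
#' a warning flag — a detector does not produce that many spikes, so mass
#' flagging indicates a detection failure, not cosmic rays.
#'
#' @param spec A [spectrum_record()].
#' @param cfg A [preprocess_config()].
#' @return `spectrum_record` with attributes `n_flagged` and `cosmic_warning`.
#' @export
remove_cosmic_rays <- function(spec, cfg = preprocess_config()) {
  y <- spec$intensities
  n <- length(y)
  stopifnot(n > cfg$cosmic_window)
  med <- runmed(y, cfg$cosmic_window, endrule = "median")
  resid <- y - med
  # floor the robust scale at a small fraction of the dynamic range so that
  # noiseless smooth spectra (MAD ~ 0) are not mass-flagged at their peaks
  s <- max(mad(resid), 1e-3 * diff(range(y)))
  flagged <- if (s > 0) abs(resid) > cfg$cosmic_k * s else rep(FALSE, n)
  warn <- FALSE
  if (sum(flagged) > 0.05 * n) {
    flagged[] <- FALSE
    warn <- TRUE
  } else if (any(flagged)) {
    idx <- seq_len(n)
    y[flagged] <- approx(idx[!flagged], y[!flagged], xout = idx[flagged],
                         rule = 2)$y
  }
  spec$intensities <- y
  attr(spec, "n_flagged") <- sum(flagged)
  attr(spec, "cosmic_warning") <- warn
  spec
}

#' Savitzky-Golay smoothing
#'
#' Endpoints are handled by the filter's asymmetric end frames (a polynomial
#' fit on the available window), so polynomials up to `smooth_polyorder` are
#' reproduced exactly across the whole spectrum. `smooth_window = 1` disables
#' smoothing.
#'
#' @param spec A [spectrum_record()].
#' @param cfg A [preprocess_config()].
#' @return The smoothed `spectrum_record`.
#' @export
smooth_spectrum <- function(spec, cfg = preprocess_config()) {
  if (cfg$smooth_window <= 1L) return(spec)
  if (cfg$smooth_window > length(spec$intensities)) {
    stop_rs("spectrum '%s': smoothing window %d exceeds spectrum length %d",
            spec$measurement_id, cfg$smooth_window, length(spec$intensities),
            class = "config_error")
  }
  spec$intensities <- as.numeric(
    signal::sgolayfilt(spec$intensities, p = cfg$smooth_polyorder,
                       n = cfg$smooth_window))
  spec
}

#' Iterative modified-polynomial fluorescence baseline
#'
#' Lieber-style modified polyfit: fit an order-`baseline_order` least-squares
#' polynomial (in the wavenumber coordinate rescaled to \[-1, 1\] for
#' conditioning); replace every intensity above the fit by the fit; refit.
#' Stops when the maximum relative change of the fit drops below
#' `baseline_tol` or after `baseline_max_iter` iterations (then the last
#' iterate is returned with `converged = FALSE` — no exception).
#'
#' @param spec A [spectrum_record()].
#' @param cfg A [preprocess_config()].
#' @return Numeric baseline vector with attributes `converged` and
#'   `iterations`.
#' @export
modpoly_baseline <- function(spec, cfg = preprocess_config()) {
  y <- spec$intensities
  w <- spec$wavenumbers
  n <- length(y)
  stopifnot(n > cfg$baseline_order + 1L)
  t <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  V <- outer(t, 0:cfg$baseline_order, `^`)
  qrV <- qr(V)
  fit_prev <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- qr.fitted(qrV, y)
    if (!is.null(fit_prev)) {
      denom <- max(abs(fit_prev), 1e-12)
      if (max(abs(fit - fit_prev)) / denom < cfg$baseline_tol) {
        converged <- TRUE
        break
      }
    }
    if (iter >= cfg$baseline_max_iter) break
    y <- pmin(y, fit)
    fit_prev <- fit
  }
  structure(as.numeric(fit), converged = converged, iterations = iter)
}

#' Intensity-response correction
#'
#' Divides by the response curve normalized to unit mean, so the overall
#' scale of the calibration lamp measurement is irrelevant.
#'
#' @param spec A [spectrum_record()].
#' @param response Strictly positive vector, same length as the spectrum.
#' @return The corrected `spectrum_record`.
#' @export
correct_intensity_response <- function(spec, response) {
  if (length(response) != length(spec$intensities)) {
    stop_rs("spectrum '%s': response length %d != %d", spec$measurement_id,
            length(response), length(spec$intensities), class = "shape_error")
  }
  if (any(response <= 0)) {
    stop_rs("spectrum '%s': response curve must be strictly positive",
            spec$measurement_id, class = "calibration_error")
  }
  spec$intensities <- spec$intensities / (response / mean(response))
  spec
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains exactly the grid points `w` with `lo <= w <= hi` (inclusive).
#'
#' @param spec A [spectrum_record()].
#' @param lo,hi Window bounds, cm^-1.
#' @return The cropped `spectrum_record`.
#' @export
crop_spectrum <- function(spec, lo = 800, hi = 1790) {
  stopifnot(lo < hi)
  keep <- spec$wavenumbers >= lo & spec$wavenumbers <= hi
  if (sum(keep) < 2L) {
    stop_rs("spectrum '%s': fewer than 2 grid points inside [%g, %g]",
            spec$measurement_id, lo, hi, class = "range_error")
  }
  spec$wavenumbers <- spec$wavenumbers[keep]
  spec$intensities <- spec$intensities[keep]
  spec
}

#' Normalize a spectrum to unit area
#'
#' Scales intensities so the trapezoid area under the curve equals one and
#' marks the spectrum as preprocessed.
#'
#' @param spec A [spectrum_record()].
#' @return The normalized `spectrum_record` (stage `"preprocessed"`).
#' @export
normalize_area <- function(spec) {
  a <- trapz_area(spec$wavenumbers, spec$intensities)
  if (!is.finite(a) || a <= 0) {
    stop_rs("spectrum '%s': area under curve is %.3g; cannot normalize",
            spec$measurement_id, a, class = "normalization_error")
  }
  spec$intensities <- spec$intensities / a
  spec$stage <- "preprocessed"
  spec
}

#' Preprocess a whole dataset
#'
#' Applies, per spectrum and in order: dark subtraction (if configured),
#' cosmic-ray removal, Savitzky-Golay smoothing, modified-polynomial baseline
#' subtraction, intensity-response correction (if configured), cropping, and
#' area normalization. The input dataset is untouched.
#'
#' @param ds A raw `spectra_dataset`.
#' @param cfg A [preprocess_config()].
#' @return A new `spectra_dataset` (all stages `"preprocessed"`) with a
#'   per-measurement QC data frame in attribute `"qc"` (`measurement_id`,
#'   `n_cosmic_flagged`, `cosmic_warning`, `baseline_converged`,
#'   `area_before`).
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  stages <- vapply(ds$spectra, `[[`, "", "stage")
  if (any(stages != "raw")) {
    stop_rs("dataset contains already-preprocessed spectra: %s",
            paste(names(stages)[stages != "raw"], collapse = ", "),
            class = "precondition_error")
  }
  qc <- vector("list", length(ds$spectra))
  out <- ds$spectra
  for (i in seq_along(out)) {
    s <- out[[i]]
    res <- tryCatch({
      if (!is.null(cfg$dark_spectrum)) s <- subtract_dark(s, cfg$dark_spectrum)
      s <- remove_cosmic_rays(s, cfg)
      n_flag <- attr(s, "n_flagged"); cwarn <- attr(s, "cosmic_warning")
      s <- smooth_spectrum(s, cfg)
      bl <- modpoly_baseline(s, cfg)
      s$intensities <- s$intensities - as.numeric(bl)
      if (!is.null(cfg$response_curve)) {
        s <- correct_intensity_response(s, cfg$response_curve)
      }
      s <- crop_spectrum(s, cfg$crop[1], cfg$crop[2])
      area_before <- trapz_area(s$wavenumbers, s$intensities)
      s <- normalize_area(s)
      attr(s, "n_flagged") <- NULL
      attr(s, "cosmic_warning") <- NULL
      list(spec = s,
           qc = data.frame(measurement_id = s$measurement_id,
                           n_cosmic_flagged = n_flag, cosmic_warning = cwarn,
                           baseline_converged = attr(bl, "converged"),
                           area_before = area_before))
    }, ramanscreen_error = function(e) {
      stop_rs("preprocessing failed for measurement '%s': %s",
              out[[i]]$measurement_id, conditionMessage(e),
              class = "stage_error")
    })
    out[[i]] <- res$spec
    qc[[i]] <- res$qc
  }
  res_ds <- spectra_dataset(out, ds$lesions, measurements = ds$measurements)
  attr(res_ds, "qc") <- do.call(rbind, qc)
  res_ds
}
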