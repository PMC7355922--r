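# Cohort data model: spectra + lesion manifest, the unit every downstream
# stage (preprocessing, cross-validation, evaluation) consumes.

VALID_LABELS <- c("melanoma", "pigmented")
VALID_STAGES <- c("raw", "preprocessed")

#' Construct a single Raman measurement record
#'
#' A spectrum is one measurement on one lesion: a strictly increasing
#' wavenumber grid (cm^-1) with matching intensities, tagged with its
#' processing stage.
#'
#' @param measurement_id,lesion_id Identifier strings.
#' @param wavenumbers Strictly increasing numeric vector, cm^-1.
#' @param intensities Numeric vector, same length as `wavenumbers`; arbitrary
#'   counts for `stage = "raw"`, unit-area normalized for `"preprocessed"`.
#' @param stage `"raw"` or `"preprocessed"`.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(measurement_id, lesion_id, wavenumbers, intensities,
                            stage = "raw") {
  stage <- match.arg(stage, VALID_STAGES)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop_rs("spectrum '%s': %d wavenumbers but %d intensities",
            measurement_id, length(wavenumbers), length(intensities),
            class = "shape_error")
  }
  if (length(wavenumbers) >= 2 && any(diff(wavenumbers) <= 0)) {
    stop_rs("spectrum '%s': wavenumbers must be strictly increasing",
            measurement_id, class = "format_error")
  }
  structure(
    list(measurement_id = as.character(measurement_id),
         lesion_id = as.character(lesion_id),
         wavenumbers = wavenumbers, intensities = intensities, stage = stage),
    class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record %s (lesion %s), %d points [%.1f, %.1f] cm^-1, stage=%s>\n",
              x$measurement_id, x$lesion_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers), x$stage))
  invisible(x)
}

#' Assemble a spectra dataset (cohort)
#'
#' Bundles measurement spectra with the lesion manifest. Construction is
#' permissive so that [validate_dataset()] can report problems; I/O and the
#' generator always return datasets that validate cleanly.
#'
#' @param spectra List of [spectrum_record()] objects.
#' @param measurements Data frame with columns `measurement_id`, `lesion_id`
#'   (one row per measurement). Defaults to the mapping carried by `spectra`.
#' @param lesions Data frame with columns `lesion_id`, `patient_id`, `label`.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(spectra, lesions, measurements = NULL) {
  stopifnot(is.list(spectra))
  if (is.null(measurements)) {
    measurements <- data.frame(
      measurement_id = vapply(spectra, `[[`, "", "measurement_id"),
      lesion_id = vapply(spectra, `[[`, "", "lesion_id"),
      stringsAsFactors = FALSE)
  }
  names(spectra) <- vapply(spectra, `[[`, "", "measurement_id")
  lesions$lesion_id <- as.character(lesions$lesion_id)
  lesions$patient_id <- as.character(lesions$patient_id)
  lesions$label <- as.character(lesions$label)
  rownames(lesions) <- NULL
  rownames(measurements) <- NULL
  structure(list(spectra = spectra, measurements = measurements,
                 lesions = lesions),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  n_mel <- sum(x$lesions$label == "melanoma")
  cat(sprintf("<spectra_dataset: %d measurements, %d lesions (%d melanoma / %d pigmented), %d patients>\n",
              length(x$spectra), nrow(x$lesions), n_mel,
              sum(x$lesions$label == "pigmented"),
              length(unique(x$lesions$patient_id))))
  invisible(x)
}

#' Number of measurements in a dataset
#' @param ds A `spectra_dataset`.
#' @return Integer count.
#' @export
n_measurements <- function(ds) length(ds$spectra)

#' Lesion-level summary table
#'
#' @param ds A `spectra_dataset`.
#' @return Data frame with `lesion_id`, `patient_id`, `label`,
#'   `n_measurements`.
#' @export
lesion_table <- function(ds) {
  counts <- table(factor(ds$measurements$lesion_id, levels = ds$lesions$lesion_id))
  out <- ds$lesions
  out$n_measurements <- as.integer(counts[out$lesion_id])
  out
}

#' Per-measurement label vector
#' @param ds A `spectra_dataset`.
#' @return Named character vector of labels, one per measurement, in dataset
#'   order.
#' @export
measurement_labels <- function(ds) {
  lab <- ds$lesions$label[match(ds$measurements$lesion_id, ds$lesions$lesion_id)]
  names(lab) <- ds$measurements$measurement_id
  lab
}

#' Intensity matrix of a dataset
#'
#' All spectra must share one wavenumber grid (use [validate_dataset()]).
#'
#' @param ds A `spectra_dataset`.
#' @return Numeric matrix, measurements x wavenumbers, with measurement ids as
#'   row names and attribute `"wavenumbers"`.
#' @export
spectra_matrix <- function(ds) {
  if (length(ds$spectra) == 0L) stop_rs("empty dataset", class = "format_error")
  grids <- vapply(ds$spectra, function(s) length(s$wavenumbers), 0L)
  if (length(unique(grids)) != 1L ||
      !all(vapply(ds$spectra, function(s)
        identical(s$wavenumbers, ds$spectra[[1]]$wavenumbers), TRUE))) {
    stop_rs("spectra do not share a common wavenumber grid", class = "grid_error")
  }
  M <- t(vapply(ds$spectra, `[[`, ds$spectra[[1]]$intensities, "intensities"))
  rownames(M) <- names(ds$spectra)
  attr(M, "wavenumbers") <- ds$spectra[[1]]$wavenumbers
  M
}

#' Validate a spectra dataset
#'
#' Checks the structural invariants: measurement ids form a bijection between
#' spectra and manifest, every lesion has at least one measurement, all
#' spectra share one wavenumber grid, per-lesion labels/patients are unique,
#' labels are known, and preprocessed spectra are cropped to 800-1790 cm^-1
#' with unit trapezoid area. Reports; never throws.
#'
#' @param ds A `spectra_dataset`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_dataset <- function(ds) {
  v <- character(0)
  spec_ids <- names(ds$spectra)
  man_ids <- ds$measurements$measurement_id
  if (anyDuplicated(spec_ids)) {
    v <- c(v, sprintf("duplicate measurement ids in spectra: %s",
                      paste(unique(spec_ids[duplicated(spec_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(man_ids)) {
    v <- c(v, sprintf("duplicate measurement ids in manifest: %s",
                      paste(unique(man_ids[duplicated(man_ids)]), collapse = ", ")))
  }
  only_spec <- setdiff(spec_ids, man_ids)
  only_man <- setdiff(man_ids, spec_ids)
  if (length(only_spec)) {
    v <- c(v, sprintf("measurements present in spectra but not in manifest: %s",
                      paste(only_spec, collapse = ", ")))
  }
  if (length(only_man)) {
    v <- c(v, sprintf("measurements present in manifest but not in spectra: %s",
                      paste(only_man, collapse = ", ")))
  }
  bad_lab <- setdiff(unique(ds$lesions$label), VALID_LABELS)
  if (length(bad_lab)) {
    v <- c(v, sprintf("unknown labels: %s", paste(bad_lab, collapse = ", ")))
  }
  if (anyDuplicated(ds$lesions$lesion_id)) {
    v <- c(v, sprintf("duplicate lesion ids: %s",
                      paste(unique(ds$lesions$lesion_id[duplicated(ds$lesions$lesion_id)]),
                            collapse = ", ")))
  }
  empty <- setdiff(ds$lesions$lesion_id, ds$measurements$lesion_id)
  if (length(empty)) {
    v <- c(v, sprintf("lesion '%s' has no measurements", empty))
  }
  orphan <- setdiff(ds$measurements$lesion_id, ds$lesions$lesion_id)
  if (length(orphan)) {
    v <- c(v, sprintf("measurement lesion '%s' missing from lesion table", orphan))
  }
  if (length(ds$spectra) >= 2L) {
    ref <- ds$spectra[[1]]
    for (s in ds$spectra[-1]) {
      if (!identical(s$wavenumbers, ref$wavenumbers)) {
        v <- c(v, sprintf("wavenumber grid of '%s' differs from '%s'",
                          s$measurement_id, ref$measurement_id))
      }
    }
  }
  for (s in ds$spectra) {
    if (s$stage == "preprocessed") {
      w <- s$wavenumbers
      if (min(w) < 800 - 1e-9 || max(w) > 1790 + 1e-9) {
        v <- c(v, sprintf("preprocessed spectrum '%s' outside 800-1790 cm^-1",
                          s$measurement_id))
      }
      a <- trapz_area(w, s$intensities)
      if (abs(a - 1) > 1e-9) {
        v <- c(v, sprintf("preprocessed spectrum '%s' has area %.3g, not 1",
                          s$measurement_id, a))
      }
    }
  }
  v
}

normalize_label <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(lab), VALID_LABELS)
  if (length(bad)) {
    stop_rs("unknown lesion label(s): %s (expected melanoma/pigmented)",
            paste(bad, collapse = ", "), class = "format_error")
  }
  lab
}

#' Read a cohort from wide-CSV spectra plus a manifest CSV
#'
#' The spectra file is wide: header `measurement_id` followed by the
#' wavenumber grid as column names, one row per measurement. The manifest has
#' columns `measurement_id`, `lesion_id`, `patient_id`, `label` (case
#' insensitive) and optionally `stage`.
#'
#' @param spectra_path,manifest_path Paths to the two CSV files.
#' @param wavenumber_calibration Optional affine pixel-to-wavenumber map
#'   `c(intercept, slope)` applied to the parsed header values.
#' @return A validated [spectra_dataset()].
#' @export
read_spectra_table <- function(spectra_path, manifest_path,
                               wavenumber_calibration = NULL) {
  sp <- data.table::fread(spectra_path, header = TRUE, sep = ",",
                          colClasses = list(character = 1L), data.table = FALSE)
  if (ncol(sp) < 1L || names(sp)[1] != "measurement_id") {
    stop_rs("spectra file '%s': first column must be 'measurement_id'",
            spectra_path, class = "format_error")
  }
  man <- data.table::fread(manifest_path, header = TRUE, sep = ",",
                           colClasses = "character", data.table = FALSE)
  need <- c("measurement_id", "lesion_id", "patient_id", "label")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop_rs("manifest '%s': missing column(s) %s", manifest_path,
            paste(miss, collapse = ", "), class = "format_error")
  }
  wn <- suppressWarnings(as.numeric(names(sp)[-1]))
  if (ncol(sp) > 1L) {
    if (anyNA(wn)) {
      stop_rs("spectra file '%s': non-numeric wavenumber column(s): %s",
              spectra_path, paste(names(sp)[-1][is.na(wn)][1:min(3, sum(is.na(wn)))],
                                  collapse = ", "), class = "format_error")
    }
    if (length(wn) >= 2 && any(diff(wn) <= 0)) {
      stop_rs("spectra file '%s': wavenumber header is not strictly increasing",
              spectra_path, class = "format_error")
    }
  }
  if (!is.null(wavenumber_calibration)) {
    stopifnot(length(wavenumber_calibration) == 2L)
    wn <- wavenumber_calibration[1] + wavenumber_calibration[2] * wn
  }

  only_spec <- setdiff(sp$measurement_id, man$measurement_id)
  only_man <- setdiff(man$measurement_id, sp$measurement_id)
  if (length(only_spec) || length(only_man)) {
    stop_rs("spectra/manifest mismatch: %s%s",
            if (length(only_spec))
              sprintf("in spectra only: %s. ", paste(only_spec, collapse = ", ")) else "",
            if (length(only_man))
              sprintf("in manifest only: %s.", paste(only_man, collapse = ", ")) else "",
            class = "consistency_error")
  }

  man$label <- normalize_label(man$label)
  man <- man[match(sp$measurement_id, man$measurement_id), , drop = FALSE]
  stage <- if ("stage" %in% names(man)) man$stage else rep("raw", nrow(man))

  spectra <- lapply(seq_len(nrow(sp)), function(i) {
    spectrum_record(sp$measurement_id[i], man$lesion_id[i], wn,
                    as.numeric(sp[i, -1]), stage = stage[i])
  })
  lesions <- unique(man[, c("lesion_id", "patient_id", "label")])
  if (anyDuplicated(lesions$lesion_id)) {
    dup <- unique(lesions$lesion_id[duplicated(lesions$lesion_id)])
    stop_rs("manifest '%s': lesion(s) %s have inconsistent patient/label rows",
            manifest_path, paste(dup, collapse = ", "), class = "consistency_error")
  }
  ds <- spectra_dataset(spectra, lesions,
                        measurements = man[, c("measurement_id", "lesion_id")])
  v <- validate_dataset(ds)
  if (length(v)) {
    stop_rs("dataset failed validation:\n- %s", paste(v, collapse = "\n- "),
            class = "consistency_error")
  }
  ds
}

#' Write a cohort to wide-CSV spectra plus a manifest CSV
#'
#' Numbers (header wavenumbers and intensities) are emitted at full decimal
#' precision so `read_spectra_table(write_spectra_table(ds))` reproduces the
#' dataset to within 1e-12.
#'
#' @param ds A valid `spectra_dataset`.
#' @param spectra_path,manifest_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra_table <- function(ds, spectra_path, manifest_path) {
  if (length(ds$spectra)) {
    grids_ok <- all(vapply(ds$spectra, function(s)
      identical(s$wavenumbers, ds$spectra[[1]]$wavenumbers), TRUE))
    if (!grids_ok) {
      stop_rs("refusing to write: spectra have mixed wavenumber grids",
              class = "grid_error")
    }
  }
  header <- if (length(ds$spectra)) {
    paste(c("measurement_id",
            sprintf("%.17g", ds$spectra[[1]]$wavenumbers)), collapse = ",")
  } else "measurement_id"
  rows <- vapply(ds$spectra, function(s) {
    paste(c(s$measurement_id, sprintf("%.17g", s$intensities)), collapse = ",")
  }, "")
  tryCatch(writeLines(c(header, rows), spectra_path),
           error = function(e) stop_rs("cannot write '%s': %s", spectra_path,
                                       conditionMessage(e), class = "io_error"))

  man <- ds$measurements
  idx <- match(man$lesion_id, ds$lesions$lesion_id)
  man$patient_id <- ds$lesions$patient_id[idx]
  man$label <- ds$lesions$label[idx]
  man$stage <- vapply(ds$spectra[man$measurement_id], `[[`, "", "stage")
  mh <- "measurement_id,lesion_id,patient_id,label,stage"
  mrows <- do.call(paste, c(unname(man[c("measurement_id", "lesion_id",
                                         "patient_id", "label", "stage")]),
                            sep = ","))
  if (nrow(man) == 0L) mrows <- character(0)
  tryCatch(writeLines(c(mh, mrows), manifest_path),
           error = function(e) stop_rs("cannot write '%s': %s", manifest_path,
                                       conditionMessage(e), class = "io_error"))
  invisible(c(spectra = spectra_path, manifest = manifest_path))
}
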