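#!/usr/bin/env Rscript
# Stage 2: raw counts -> unit-area fingerprint spectra. Chain: cosmic-ray
# removal, Savitzky-Golay smoothing (window 11, order 3), iterative
# fifth-order modified-polynomial fluorescence-baseline subtraction, crop to
# 800-1790 cm^-1, area normalization. Per-measurement QC flags are kept.

library(ramanscreen)

ds <- read_spectra_table("results/raw_spectra.csv", "results/raw_manifest.csv")
pre <- preprocess_dataset(ds, preprocess_config())

qc <- attr(pre, "qc")
cat(sprintf("preprocessed %d spectra\n", n_measurements(pre)))
cat(sprintf("cosmic points repaired: %d (warnings: %d)\n",
            sum(qc$n_cosmic_flagged), sum(qc$cosmic_warning)))
cat(sprintf("baseline fits converged: %d / %d\n",
            sum(qc$baseline_converged), nrow(qc)))
stopifnot(length(validate_dataset(pre)) == 0L)

write_spectra_table(pre, "results/preprocessed_spectra.csv",
                    "results/manifest.csv")
data.table::fwrite(qc, "results/qc.csv")
cat("wrote results/preprocessed_spectra.csv, results/manifest.csv, results/qc.csv\n")
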