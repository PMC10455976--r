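#!/usr/bin/env Rscript
# Pre-treat the raw spectra the way the tissue study does: cut to the
# 1800-900 cm^-1 fingerprint region (235 wavenumbers), rubber-band baseline
# correction, normalisation to the amide I peak (1700-1600 cm^-1), then
# average the 10 replicate point spectra per specimen.

library(ftirqda)

raw <- read_dataset("results/data/spectra_raw_wide.csv", layout = "wide")
pp <- preprocess_pipeline(raw, preprocess_config())
ds <- average_replicates(pp)

write_dataset(ds, "results/data/spectra_preprocessed_wide.csv", layout = "wide")

cat(sprintf("fingerprint region: %d wavenumbers (%.1f..%.1f cm^-1)\n",
            length(ds$wavenumbers), max(ds$wavenumbers), min(ds$wavenumbers)))
cat(sprintf("%d per-specimen spectra written\n", nrow(ds$absorbance)))
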