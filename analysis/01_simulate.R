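#!/usr/bin/env Rscript
# Generate the synthetic six-class ATR-FTIR tissue dataset under the study
# conditions: 109 specimens (35 normal / 13 inflammatory / 26 Barrett's /
# 4 LGD / 9 HGD / 22 OAC), 10 replicate point spectra each, 4000-600 cm^-1
# grid, with the normal and inflammatory band-amplitude means coinciding
# (overlap = 1) so the two classes are spectrally confusable.

library(ftirqda)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_spectra(generator_config(seed = seed))
ds <- sim$dataset

write_dataset(ds, file.path(out, "spectra_raw_wide.csv"), layout = "wide")
write.csv(data.frame(specimen_id = sim$truth$specimen_id,
                     class = sim$truth$class,
                     sim$truth$amplitudes),
          file.path(out, "truth_amplitudes.csv"), row.names = FALSE)

cat("specimens per class:\n")
print(class_counts(ds))
cat(sprintf("%d spectra x %d wavenumbers written to %s\n",
            nrow(ds$absorbance), length(ds$wavenumbers), out))
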