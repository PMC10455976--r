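#!/usr/bin/env Rscript
# Model robustness: bootstrap out-of-bag misclassification probability for
# each pipeline, and Mann-Whitney confirmation of the SPA-selected
# wavenumbers between the Barrett's and OAC classes.

library(ftirqda)

ds <- read_dataset("results/data/spectra_preprocessed_wide.csv", "wide")

specs <- list(
  "pca-qda" = model_spec("pca-qda", n_components = 6),
  "spa-qda" = model_spec("spa-qda", max_vars = 6),
  "ga-qda" = model_spec("ga-qda",
                        ga = ga_config(generations = 15, population = 40,
                                       restarts = 1, min_vars = 2,
                                       max_vars = 8)))

rob <- data.frame(model = names(specs), misclassification_probability = NA)
for (i in seq_along(specs)) {
  est <- bootstrap_misclassification(ds, specs[[i]], replicates = 100,
                                     seed = 6)
  rob$misclassification_probability[i] <- est$probability
  cat(sprintf("%-8s misclassification probability %.3f\n",
              names(specs)[i], est$probability))
}
write.csv(rob, "results/robustness.csv", row.names = FALSE)

sel <- read.csv("results/selected_spa_qda.csv")
mw <- mann_whitney_bands(ds, sel$index, c("barretts", "oac"))
print(mw)
write.csv(mw, "results/mann_whitney_spa_barretts_oac.csv", row.names = FALSE)
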