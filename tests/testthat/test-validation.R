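test_that("stratified splits hold out the rounded per-class counts", {
  labels <- rep(tissue_classes(), c(35, 13, 26, 4, 9, 22))
  plan <- mc_plan(iterations = 5, seed = 3)
  splits <- make_splits(labels, plan)
  expect_length(splits, 5)
  for (sp in splits) {
    expect_equal(sort(c(sp$train, sp$validation)), seq_along(labels))
    expect_length(intersect(sp$train, sp$validation), 0)
    held <- table(factor(labels[sp$validation], levels = tissue_classes()))
    expect_equal(unname(c(held)), c(7, 3, 5, 1, 2, 4))
  }
  # reproducibility from the seed
  expect_identical(splits, make_splits(labels, plan))
  # degenerate plans error
  expect_error(mc_plan(hold_out_fraction = 0), class = "ftirqda_plan_error")
  expect_error(make_splits(labels, mc_plan(hold_out_fraction = 1e-4)),
               class = "ftirqda_plan_error")
  expect_error(make_splits(c("normal", "oac", "oac"), mc_plan()),
               class = "ftirqda_plan_error")
})

test_that("figures of merit reproduce the printed worked rows", {
  # confusion row: 25 of 35 normal correct, 10 predicted inflammatory
  cm_pca <- diag(c(25, 13, 26, 4, 9, 22))
  cm_pca[1, 2] <- 10
  dimnames(cm_pca) <- list(tissue_classes(), tissue_classes())
  f <- figures_of_merit(cm_pca)
  expect_equal(round(f$sensitivity[[1]], 1), 71.4)
  expect_equal(f$sensitivity[[2]], 100)
  expect_equal(round(f$accuracy, 1), round(100 * 99 / 109, 1))

  # confusion row: 10 of 35 normal correct, 25 predicted inflammatory
  cm_ga <- diag(c(10, 0, 26, 4, 9, 22))
  cm_ga[1, 2] <- 25
  cm_ga[2, 1] <- 13
  f2 <- figures_of_merit(cm_ga)
  expect_equal(round(f2$sensitivity[[1]], 1), 28.6)
  expect_equal(f2$sensitivity[[2]], 0)

  # identity permutation scores 100 everywhere
  perm <- diag(6)[, ]
  fp <- figures_of_merit(perm)
  expect_equal(unname(fp$sensitivity), rep(100, 6))
  expect_equal(unname(fp$specificity), rep(100, 6))
  expect_equal(fp$accuracy, 100)
  # undefined denominators are NA, not zero
  cm0 <- diag(c(0, 5)); cm0[1, 2] <- 0
  expect_true(is.na(figures_of_merit(cm0)$sensitivity[[1]]))
})

test_that("the F-score is the harmonic mean with the documented endpoints", {
  expect_equal(round(fscore(71.4, 100.0), 1), 83.3)
  expect_equal(round(fscore(100.0, 89.5), 1), 94.5)
  expect_equal(round(fscore(100.0, 80.0), 1), 88.9)
  expect_equal(round(fscore(28.6, 80.0), 1), 42.1)
  expect_equal(fscore(100, 100), 100)
  expect_equal(as.numeric(fscore(0, 80)), 0)
  for (s in c(12.5, 50, 97.3)) expect_equal(fscore(s, s), s)
  z <- fscore(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "degenerate"), 1L)
})

test_that("largest-remainder rescaling conserves class row sums", {
  sim <- generate_spectra(generator_config(
    class_sizes = c(normal = 6, barretts = 5, oac = 5),
    replicates = 2, separation = 10, overlap = 0, seed = 5))
  ds <- average_replicates(preprocess_pipeline(sim$dataset))
  res <- run_mccv(ds, model_spec("pca-qda"), mc_plan(iterations = 7, seed = 2))
  expect_equal(unname(rowSums(res$confusion)),
               unname(class_counts(ds)[rownames(res$confusion)]))
})

test_that("perfectly separated classes give a diagonal confusion and 100% FOM", {
  sim <- generate_spectra(generator_config(
    class_sizes = c(normal = 8, inflammatory = 6, oac = 7),
    replicates = 3, separation = 10, overlap = 0, seed = 11))
  ds <- average_replicates(preprocess_pipeline(sim$dataset))
  res <- run_mccv(ds, model_spec("pca-qda"), mc_plan(iterations = 10, seed = 4))
  expect_equal(res$accuracy_mean, 100)
  present <- rowSums(res$confusion) > 0
  expect_equal(res$confusion[present, present],
               diag(class_counts(ds)[rownames(res$confusion)][present]),
               ignore_attr = TRUE)
  expect_equal(res$fom$sensitivity[present], rep(100, 3))
  # a single iteration equals one stratified hold-out evaluation
  one <- run_mccv(ds, model_spec("pca-qda"), mc_plan(iterations = 1, seed = 4))
  expect_equal(sum(one$confusion_raw),
               sum(make_splits(as.character(ds$meta$class),
                               mc_plan(iterations = 1, seed = 4))[[1]]$validation > 0))
})

test_that("bootstrap misclassification is near zero for separable classes and reproducible", {
  sim <- generate_spectra(generator_config(
    class_sizes = c(normal = 8, barretts = 8, oac = 8),
    replicates = 2, separation = 10, overlap = 0, seed = 21))
  ds <- average_replicates(preprocess_pipeline(sim$dataset))
  r1 <- bootstrap_misclassification(ds, model_spec("pca-qda"),
                                    replicates = 60, seed = 9)
  r2 <- bootstrap_misclassification(ds, model_spec("pca-qda"),
                                    replicates = 60, seed = 9)
  expect_lt(r1$probability, 0.02)
  expect_identical(r1$per_specimen, r2$per_specimen)
})

test_that("Mann-Whitney band tests give exact small-sample p-values", {
  wn <- seq(1800, 900, length.out = 5)
  ab <- rbind(matrix(rep(c(1, 2, 3), 5), 3), matrix(rep(c(10, 11, 12), 5), 3))
  ds <- spectral_dataset(wn, ab,
                         data.frame(specimen_id = paste0("s", 1:6),
                                    replicate = 1,
                                    class = rep(c("normal", "oac"), each = 3)))
  mw <- mann_whitney_bands(ds, 1:2, c("normal", "oac"))
  expect_equal(mw$p_value, rep(0.1, 2)) # U = 0, n = m = 3, two-sided exact
  expect_false(any(mw$significant))

  # identical distributions give p = 1; constant identical groups are flagged
  ab2 <- rbind(ab[1:3, ], ab[1:3, ])
  ds2 <- spectral_dataset(wn, ab2, ds$meta)
  mw2 <- mann_whitney_bands(ds2, 1:3, c("normal", "oac"))
  expect_equal(mw2$p_value, rep(1, 3))
  ds3 <- spectral_dataset(wn, matrix(1, 6, 5), ds$meta)
  mw3 <- mann_whitney_bands(ds3, 1, c("normal", "oac"))
  expect_equal(mw3$p_value, 1)
  expect_true(mw3$degenerate)

  # rank-based: invariant under monotone transforms of absorbance
  ds4 <- ds
  ds4$absorbance <- exp(ds$absorbance / 5)
  mw4 <- mann_whitney_bands(ds4, 1:5, c("normal", "oac"))
  expect_equal(mw4$p_value, mann_whitney_bands(ds, 1:5, c("normal", "oac"))$p_value)
})
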