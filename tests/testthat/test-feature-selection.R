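test_that("squared Mahalanobis distance matches hand arithmetic", {
  expect_equal(mahalanobis_sq(c(0, 0), c(0, 0), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(3, 4), c(0, 0), diag(2)), 25) # Euclidean
  expect_equal(mahalanobis_sq(c(1, 0), c(0, 0), diag(c(4, 1))), 0.25)
  expect_error(mahalanobis_sq(c(1, 0), c(0, 0), matrix(1, 2, 2)),
               class = "ftirqda_singularity_error")
})

test_that("risk G matches hand arithmetic on a 1-D two-class problem", {
  # means 0 and 4, pooled variance 1; point x = 1 of class 1: g = 1/9
  train_x <- matrix(c(-1, 0, 1, 3, 4, 5), ncol = 1)
  train_y <- rep(c("a", "b"), each = 3)
  r <- risk_G(train_x, train_y, matrix(1), "a")
  expect_equal(r$G, 1 / 9)
  expect_equal(r$NV, 1)
  # validation points exactly at their own class means give G = 0
  r0 <- risk_G(train_x, train_y, matrix(c(0, 4), ncol = 1), c("a", "b"))
  expect_equal(r0$G, 0)
  # a point exactly at a wrong-class centre is flagged as infinite risk
  rinf <- risk_G(train_x, train_y, matrix(4), "a")
  expect_equal(rinf$G, Inf)
  expect_equal(rinf$n_degenerate, 1)
})

test_that("risk G equals the brute-force oracle on random instances", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    d <- sample(2:4, 1)
    toy <- toy_problem(n_per = sample(5:9, 1), d = d, k = k,
                       sep = runif(1, 1, 4), seed = rep + 100)
    n <- nrow(toy$X)
    va <- sample(n, round(n / 4))
    tr <- setdiff(seq_len(n), va)
    got <- risk_G(toy$X[tr, ], toy$y[tr], toy$X[va, , drop = FALSE],
                  toy$y[va])$G
    want <- oracle_risk_G(toy$X[tr, ], toy$y[tr],
                          toy$X[va, , drop = FALSE], toy$y[va])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("risk G with per-class covariance is invariant under linear maps", {
  toy <- toy_problem(n_per = 12, d = 3, k = 3, seed = 23)
  n <- nrow(toy$X)
  va <- seq(1, n, by = 4)
  tr <- setdiff(seq_len(n), va)
  base <- risk_G(toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va],
                 covariance_mode = "per-class")$G
  set.seed(31)
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
    got <- risk_G(toy$X[tr, ] %*% A, toy$y[tr], toy$X[va, ] %*% A,
                  toy$y[va], covariance_mode = "per-class")$G
    expect_equal(got, base, tolerance = 1e-6)
  }
})

test_that("SPA at chain length 1 equals the exhaustive single-variable scan", {
  pb <- make_selection_problem()
  res <- spa_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y,
                    max_vars = 1)
  exhaustive <- sapply(seq_len(ncol(pb$train_x)), function(j) {
    risk_G(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y, j)$G
  })
  expect_equal(res$selected, which.min(exhaustive))
  expect_equal(res$G, min(exhaustive))
})

test_that("SPA recovers the informative pair and never repeats an index", {
  pb <- make_selection_problem()
  res <- spa_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y,
                    max_vars = 2)
  expect_setequal(res$selected, c(1, 2))
  # exhaustive check over all pairs: SPA's pair is the global pair optimum
  pairs <- combn(ncol(pb$train_x), 2)
  pairG <- apply(pairs, 2, function(v) {
    risk_G(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y, v)$G
  })
  expect_lte(res$G, min(pairG) + 1e-12)
  res4 <- spa_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y,
                     max_vars = 4)
  expect_equal(anyDuplicated(res4$selected), 0)
  expect_error(spa_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y,
                          max_vars = 99),
               class = "ftirqda_config_error")
})

test_that("the GA is reproducible, monotone under elitism, and finds small optima", {
  pb <- make_selection_problem(seed = 5, n_noise = 6) # 8 features total
  cfg <- ga_config(generations = 15, population = 30, restarts = 2,
                   min_vars = 1, max_vars = 4, seed = 99)
  r1 <- ga_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y, cfg)
  r2 <- ga_select(pb$train_x, pb$train_y, pb$valid_x, pb$valid_y, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  for (r in seq_len(ncol(r1$trace))) {
    expect_true(all(diff(r1$trace[, r]) <= 1e-12))
  }
  expect_true(all(r1$selected %in% seq_len(8)))
  expect_error(ga_config(population = 1), class = "ftirqda_config_error")
})

test_that("selection reports map indices to descending wavenumbers", {
  wn <- seq(1800, 900, length.out = 235)
  rep6 <- selection_report(list(selected = c(10, 200, 3, 50, 101, 7), G = 0.2),
                           wn)
  expect_equal(nrow(rep6), 6)
  expect_true(all(diff(rep6$wavenumber) < 0))
  expect_equal(attr(rep6, "n_vars"), 6)
  rep25 <- selection_report(list(selected = round(seq(5, 230, length.out = 25)),
                                 G = 0.1), wn)
  expect_equal(nrow(rep25), 25)
  expect_error(selection_report(list(selected = integer(0), G = 1), wn),
               class = "ftirqda_config_error")
})
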