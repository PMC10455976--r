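test_that("PCA finds the intrinsic dimension of planar data", {
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  X <- matrix(rnorm(60), 30, 2) %*% t(basis) # exactly 2-D in 10-D
  p <- fit_pca(X, var_target = 0.99)
  expect_equal(p$n_components, 2)
  expect_equal(sum(p$explained[1:2]), 1, tolerance = 1e-10)
  # orthonormal loadings, reconstruction at full rank
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  sc <- pca_project(p, X)
  expect_equal(sc %*% t(p$loadings) + rep(1, 30) %o% p$center, X,
               tolerance = 1e-9)
})

test_that("PCA explained variances match a brute-force eigendecomposition", {
  set.seed(8)
  X <- matrix(rnorm(9), 3, 3)
  p <- fit_pca(X, n_components = 2)
  ev <- sort(eigen(cov(X), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(p$explained * sum(ev), pmax(ev, 0), tolerance = 1e-9)
  # projecting the training mean gives the zero score vector
  expect_equal(as.numeric(pca_project(p, colMeans(X))), c(0, 0),
               tolerance = 1e-12)
  # toy scores equal the brute-force centred product
  centred <- sweep(X, 2, colMeans(X))
  expect_equal(pca_project(p, X), centred %*% p$loadings)
  expect_error(fit_pca(X, n_components = 3), class = "ftirqda_dimension_error")
})

test_that("QDA fit matches hand-computed means and covariances", {
  X <- matrix(c(-1, 0, 1, 2, 3, 4), ncol = 1)
  y <- c("c1", "c1", "c1", "c2", "c2", "c2")
  m <- fit_qda(X, y, lambda = 0)
  expect_equal(as.numeric(m$means), c(0, 3))
  expect_equal(m$covariances[[1]][1, 1], 1)
  expect_equal(m$covariances[[2]][1, 1], 1)
  expect_equal(m$priors, c(0.5, 0.5))
  # lambda = 1 collapses every class onto the pooled covariance
  set.seed(2)
  X2 <- matrix(rnorm(40), 20, 2)
  y2 <- rep(c("a", "b"), each = 10)
  m2 <- fit_qda(X2, y2, lambda = 1)
  expect_equal(m2$covariances[[1]], m2$covariances[[2]])
  expect_error(fit_qda(matrix(rnorm(3), ncol = 1), c("a", "a", "b"),
                       lambda = 0),
               class = "ftirqda_singularity_error")
})

test_that("a tiny class with shrinkage still yields a positive-definite covariance", {
  set.seed(9)
  X <- rbind(matrix(rnorm(4 * 6), 4, 6),        # LGD-sized class: n = 4, d = 6
             matrix(rnorm(20 * 6) + 3, 20, 6))
  y <- c(rep("lgd", 4), rep("oac", 20))
  m <- fit_qda(X, y, lambda = 0.5)
  for (S in m$covariances) {
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("discriminant scores match hand arithmetic and the density oracle", {
  # single class at the origin, identity covariance, prior 1: Q = 0 at the mean
  one <- fit_qda(rbind(diag(2), -diag(2)), rep("a", 4), lambda = 0)
  stopifnot(max(abs(one$covariances[[1]] - diag(2) * 2/3)) < 1e-12)
  m0 <- one
  m0$covariances[[1]] <- diag(2); m0$chol[[1]] <- diag(2); m0$log_dets[1] <- 0
  expect_equal(as.numeric(qda_score(m0, c(0, 0))), 0)

  # 1-D two-class model, equal priors, equidistant point: both scores
  # (1.5)^2 - 2 log(1/2) and the tie is broken to the first class
  m <- fit_qda(matrix(c(-1, 0, 1, 2, 3, 4), ncol = 1),
               rep(c("c1", "c2"), each = 3), lambda = 0)
  q <- qda_score(m, 1.5)
  expect_equal(as.numeric(q), rep(2.25 + 2 * log(2), 2), tolerance = 1e-12)
  pr <- predict(m, matrix(c(-1, 1.5, 4), ncol = 1))
  expect_equal(as.character(pr$class), c("c1", "c1", "c2"))

  # Q = -2 log(pi_k phi_k(x)) - d log(2 pi) against the density oracle
  toy <- toy_problem(n_per = 10, d = 3, k = 3, seed = 4)
  mm <- fit_qda(toy$X, toy$y, lambda = 0)
  set.seed(14)
  pts <- matrix(rnorm(200 * 3, sd = 4), 200, 3)
  Q <- qda_score(mm, pts)
  for (i in c(1, 57, 200)) {
    for (k in 1:3) {
      expect_equal(as.numeric(Q[i, k]),
                   as.numeric(oracle_qda_score(pts[i, ], mm$means[k, ],
                                               mm$covariances[[k]],
                                               mm$priors[k])),
                   tolerance = 1e-9)
    }
  }
  # prediction equals the brute-force posterior argmax everywhere
  post <- t(apply(pts, 1, function(x) {
    sapply(1:3, function(k) log(mm$priors[k]) +
             oracle_log_dmvnorm(x, mm$means[k, ], mm$covariances[[k]]))
  }))
  expect_equal(as.integer(predict(mm, pts)$class), apply(post, 1, which.max))
})

test_that("predictions are invariant under invertible affine maps at lambda 0", {
  toy <- toy_problem(n_per = 12, d = 3, k = 3, seed = 6)
  m <- fit_qda(toy$X, toy$y, lambda = 0)
  set.seed(21)
  pts <- matrix(rnorm(50 * 3, sd = 4), 50, 3)
  base <- predict(m, pts)$class
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
    b <- rnorm(3)
    f <- function(X) sweep(X %*% t(A), 2, -b)
    mt <- fit_qda(f(toy$X), toy$y, lambda = 0)
    expect_equal(as.character(predict(mt, f(pts))$class), as.character(base))
  }
})

test_that("equal covariances and priors reduce QDA to nearest Mahalanobis mean", {
  toy <- toy_problem(n_per = 15, d = 2, k = 3, seed = 10)
  m <- fit_qda(toy$X, toy$y, priors = "uniform", lambda = 1)
  set.seed(33)
  pts <- matrix(rnorm(40 * 2, sd = 5), 40, 2)
  S <- m$covariances[[1]]
  nearest <- apply(pts, 1, function(x) {
    which.min(sapply(1:3, function(k) stats::mahalanobis(x, m$means[k, ], S)))
  })
  expect_equal(as.integer(predict(m, pts)$class), nearest)
})
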