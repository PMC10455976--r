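# Independent brute-force oracles used to cross-check the implementation.
# They deliberately take different computational routes (explicit inverses,
# pairwise enumeration, density formulas) from the package code.

# lower convex hull baseline by pairwise supporting-line enumeration:
# at each x the baseline is the largest value of any line through two data
# points that keeps every data point on or above it
oracle_lower_hull <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (j in 1:(n - 1)) {
    for (k in (j + 1):n) {
      slope <- (y[k] - y[j]) / (x[k] - x[j])
      line <- y[j] + slope * (x - x[j])
      if (all(y - line >= -1e-9 * max(1, abs(y)))) {
        base <- pmax(base, line)
      }
    }
  }
  base
}

# multivariate Gaussian log-density via explicit inverse and determinant
# (kept in log space so far-away points do not underflow)
oracle_log_dmvnorm <- function(x, mu, S) {
  d <- length(mu)
  diff <- as.numeric(x - mu)
  -0.5 * (d * log(2 * pi) + log(det(S)) +
            as.numeric(t(diff) %*% solve(S) %*% diff))
}

# discriminant score from the density: Q = -2 log(pi_k phi_k) - d log(2 pi)
oracle_qda_score <- function(x, mu, S, prior) {
  d <- length(mu)
  -2 * (log(prior) + oracle_log_dmvnorm(x, mu, S)) - d * log(2 * pi)
}

# risk cost G by an explicit loop over validation points and classes,
# using stats::mahalanobis and a hand-pooled covariance
oracle_risk_G <- function(train_x, train_y, valid_x, valid_y) {
  classes <- unique(train_y)
  d <- ncol(train_x)
  pooled <- matrix(0, d, d)
  dfree <- 0
  means <- list()
  for (k in classes) {
    Xk <- train_x[train_y == k, , drop = FALSE]
    means[[k]] <- colMeans(Xk)
    pooled <- pooled + (nrow(Xk) - 1) * cov(Xk)
    dfree <- dfree + nrow(Xk) - 1
  }
  pooled <- pooled / dfree
  gn <- numeric(nrow(valid_x))
  for (i in seq_len(nrow(valid_x))) {
    r2 <- sapply(classes, function(k) {
      stats::mahalanobis(valid_x[i, ], means[[k]], pooled)
    })
    own <- r2[[valid_y[i]]]
    gn[i] <- own / min(r2[names(r2) != valid_y[i]])
  }
  mean(gn)
}

# small labelled Gaussian classification problem with well-separated means
toy_problem <- function(n_per = 8, d = 3, k = 3, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep(paste0("c", seq_len(k)), each = n_per)
  mu <- matrix(rnorm(k * d), k, d) * sep
  X <- mu[rep(seq_len(k), each = n_per), ] + matrix(rnorm(n_per * k * d), ncol = d)
  list(X = X, y = y)
}

# wavenumber-selection toy: two informative coordinates separate three
# classes, the remaining columns are pure noise
make_selection_problem <- function(seed = 2, n_noise = 6) {
  set.seed(seed)
  y <- rep(c("a", "b", "c"), each = 10)
  mu <- rbind(c(0, 0), c(6, 0), c(0, 6))
  inf <- mu[rep(1:3, each = 10), ] + matrix(rnorm(60, 0, 0.5), ncol = 2)
  X <- cbind(inf, matrix(rnorm(30 * n_noise), ncol = n_noise))
  va <- seq(1, 30, by = 3)
  list(train_x = X[-va, ], train_y = y[-va],
       valid_x = X[va, ], valid_y = y[va])
}

# tiny spectral dataset built by hand (2 specimens x 2 replicates)
tiny_dataset <- function(n_wn = 20) {
  wn <- seq(1800, 900, length.out = n_wn)
  set.seed(42)
  ab <- matrix(runif(4 * n_wn, 0.1, 1), 4, n_wn)
  spectral_dataset(wn, ab,
                   data.frame(specimen_id = rep(c("a", "b"), each = 2),
                              replicate = rep(1:2, 2),
                              class = rep(c("normal", "oac"), each = 2)))
}
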