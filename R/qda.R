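#' Fit a mean-centred PCA projection
#'
#' Front-end for PCA-QDA: principal components of the preprocessed spectra,
#' retained either as a fixed count or as the smallest count reaching a
#' cumulative explained-variance target (optionally capped). Component signs
#' are fixed by making each loading's largest-magnitude entry positive, so
#' the projection is deterministic.
#'
#' @param X Numeric matrix, samples in rows.
#' @param n_components Integer count of components to keep, or `NULL` to
#'   use `var_target`.
#' @param var_target Cumulative explained-variance fraction in (0, 1); the
#'   smallest component count reaching it is kept.
#' @param max_components Optional cap on the retained count (the study
#'   operating point is a 0.935 target capped at 6 components).
#' @return Object of class `pca_projection`: `center`, `loadings`
#'   (orthonormal columns), `explained` (variance fractions, all
#'   components), `n_components`.
#' @export
fit_pca <- function(X, n_components = NULL, var_target = NULL,
                    max_components = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) ftir_error("PCA needs at least 2 samples", "dimension_error")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  frac <- ev / sum(ev)
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_components)) {
    if (is.null(var_target)) ftir_error("give n_components or var_target", "config_error")
    m <- which(cumsum(frac) >= var_target - 1e-12)[1]
    if (is.na(m)) m <- rank
    if (!is.null(max_components)) m <- min(m, max_components)
  } else {
    m <- as.integer(n_components)
    if (m > min(nrow(X) - 1L, ncol(X)) || m > rank) {
      ftir_error(sprintf("requested %d components but rank is %d", m, rank),
                 "dimension_error")
    }
  }
  m <- min(m, rank)
  load <- pr$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(center = pr$center, loadings = load, explained = frac,
                 n_components = m),
            class = "pca_projection")
}

#' Project samples onto a fitted PCA basis
#'
#' @param p A `pca_projection` from [fit_pca()].
#' @param X Numeric matrix (or vector) with the training feature count.
#' @return Score matrix, one row per sample, `p$n_components` columns.
#' @export
pca_project <- function(p, X) {
  stopifnot(inherits(p, "pca_projection"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(p$center)) {
    ftir_error("feature count does not match the PCA fit", "dimension_error")
  }
  sweep(X, 2, p$center) %*% p$loadings
}

# upper-triangular Cholesky with escalating trace-scaled ridge; keeps the
# discriminant well defined for tiny or duplicated classes
chol_ridge <- function(S, start = 1e-8) {
  d <- nrow(S)
  S <- (S + t(S)) / 2
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ridge <- 0
  for (k in 0:24) {
    R <- tryCatch(chol(S + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(R) && all(diag(R) > 0)) {
      return(list(R = R, logdet = 2 * sum(log(diag(R))), ridge = ridge))
    }
    ridge <- if (ridge == 0) start * scale else ridge * 10
  }
  ftir_error("covariance could not be made positive definite", "singularity_error")
}

#' Fit a quadratic discriminant model
#'
#' Per-class Gaussian model: class means, class variance-covariance
#' matrices (denominator `n_k - 1`) and priors. Because some tissue classes
#' are tiny (low-grade dysplasia has 4 specimens) the raw class covariances
#' can be singular; each is shrunk toward the pooled covariance by weight
#' `lambda`, with a trace-scaled ridge fallback if a matrix is still not
#' positive definite.
#'
#' @param X Feature matrix, samples in rows.
#' @param y Class labels (factor or character); every class needs >= 2
#'   samples unless `lambda > 0`.
#' @param priors `"empirical"` (class frequencies, default) or `"uniform"`.
#' @param lambda Shrinkage weight in `[0, 1]` toward the pooled covariance
#'   (`lambda = 1` collapses all classes onto the pooled matrix).
#' @return Object of class `qda_model`: `classes`, `means`, `covariances`,
#'   Cholesky factors, `log_dets`, `priors`, `lambda`.
#' @export
fit_qda <- function(X, y, priors = c("empirical", "uniform"), lambda = 0.5) {
  X <- as.matrix(X)
  priors <- match.arg(priors)
  if (lambda < 0 || lambda > 1) ftir_error("lambda must be in [0, 1]", "config_error")
  y <- factor(as.character(y))
  classes <- levels(y)
  K <- length(classes)
  d <- ncol(X)
  nk <- as.integer(table(y)[classes])
  if (any(nk < 2) && lambda == 0) {
    ftir_error("a class has fewer than 2 samples; use lambda > 0 so its covariance shrinks toward the pooled matrix",
               "singularity_error")
  }
  if (any(nk < 1)) ftir_error("every class needs at least one sample", "singularity_error")

  means <- matrix(0, K, d)
  covs <- vector("list", K)
  pooled <- matrix(0, d, d)
  dfree <- 0
  for (k in seq_len(K)) {
    Xk <- X[y == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    Sk <- if (nrow(Xk) >= 2) stats::cov(Xk) else matrix(0, d, d)
    covs[[k]] <- Sk
    if (nrow(Xk) >= 2) {
      pooled <- pooled + (nrow(Xk) - 1) * Sk
      dfree <- dfree + nrow(Xk) - 1
    }
  }
  pooled <- if (dfree > 0) pooled / dfree else diag(d)
  chols <- vector("list", K)
  logdets <- numeric(K)
  for (k in seq_len(K)) {
    covs[[k]] <- (1 - lambda) * covs[[k]] + lambda * pooled
    cr <- chol_ridge(covs[[k]])
    covs[[k]] <- covs[[k]] + diag(cr$ridge, d)
    chols[[k]] <- cr$R
    logdets[k] <- cr$logdet
  }
  pk <- if (priors == "empirical") nk / sum(nk) else rep(1 / K, K)
  structure(list(classes = classes, means = means, covariances = covs,
                 chol = chols, log_dets = logdets, priors = pk,
                 lambda = lambda, d = d),
            class = "qda_model")
}

#' Quadratic discriminant scores
#'
#' For each sample and class k the penalised squared Mahalanobis distance
#' `Q_ik = (x - xbar_k)' Sigma_k^{-1} (x - xbar_k) + log|Sigma_k|
#' - 2 log(pi_k)`, computed through the Cholesky factor of `Sigma_k`
#' (never an explicit inverse). Equals `-2 log(pi_k phi_k(x)) - d log(2 pi)`
#' where `phi_k` is the class Gaussian density; classification picks the
#' minimum.
#'
#' @param model A [fit_qda()] model.
#' @param X Feature matrix or single vector.
#' @return Matrix of scores, one row per sample, one column per class.
#' @export
qda_score <- function(model, X) {
  stopifnot(inherits(model, "qda_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$d) ftir_error("feature count mismatch", "dimension_error")
  if (any(!is.finite(X))) ftir_error("non-finite input", "format_error")
  K <- length(model$classes)
  Q <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, model$classes))
  for (k in seq_len(K)) {
    cent <- t(X) - model$means[k, ]
    v <- backsolve(model$chol[[k]], cent, transpose = TRUE)
    Q[, k] <- colSums(v^2) + model$log_dets[k] - 2 * log(model$priors[k])
  }
  Q
}

#' Classify samples with a quadratic discriminant model
#'
#' Assigns each sample the class with the minimum discriminant score; exact
#' ties go to the class with the larger prior, then to the earlier class in
#' the model's class order.
#'
#' @param object A [fit_qda()] model.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return List with `class` (factor over the model's classes) and `scores`
#'   (the full score matrix, for audit).
#' @export
predict.qda_model <- function(object, newdata, ...) {
  Q <- qda_score(object, newdata)
  pick <- apply(Q, 1, function(q) {
    order(q, -object$priors, seq_along(q))[1]
  })
  list(class = factor(object$classes[pick], levels = object$classes),
       scores = Q)
}
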