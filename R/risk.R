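#' Squared Mahalanobis distance
#'
#' `r2 = (x - centre)' S^{-1} (x - centre)`, computed through the Cholesky
#' factor of `S`.
#'
#' @param x Numeric vector (or matrix of row vectors).
#' @param centre Class mean vector.
#' @param S Covariance matrix, positive definite on the selected variables.
#' @return Non-negative scalar (or vector), zero iff `x == centre`.
#' @export
mahalanobis_sq <- function(x, centre, S) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  S <- as.matrix(S)
  R <- tryCatch(chol((S + t(S)) / 2), error = function(e) {
    ftir_error("singular covariance: use a pooled or regularised covariance for the Mahalanobis metric",
               "singularity_error")
  })
  v <- backsolve(R, t(x) - as.numeric(centre), transpose = TRUE)
  colSums(v^2)
}

# class means and the covariance(s) defining the Mahalanobis metric,
# estimated on the training block restricted to `variables`
risk_metric <- function(train_x, train_y, variables, covariance_mode,
                        shrinkage = 0.5) {
  Xs <- train_x[, variables, drop = FALSE]
  y <- factor(as.character(train_y))
  classes <- levels(y)
  means <- lapply(classes, function(k) colMeans(Xs[y == k, , drop = FALSE]))
  if (covariance_mode == "pooled") {
    d <- ncol(Xs)
    pooled <- matrix(0, d, d)
    dfree <- 0
    for (k in classes) {
      Xk <- Xs[y == k, , drop = FALSE]
      if (nrow(Xk) >= 2) {
        pooled <- pooled + (nrow(Xk) - 1) * stats::cov(Xk)
        dfree <- dfree + nrow(Xk) - 1
      }
    }
    if (dfree == 0) ftir_error("no class has 2 training samples", "singularity_error")
    pooled <- pooled / dfree
    cr <- chol_ridge(pooled)
    chols <- rep(list(cr$R), length(classes))
  } else {
    m <- fit_qda(Xs, y, lambda = shrinkage)
    chols <- m$chol[match(classes, m$classes)]
  }
  list(classes = classes, means = means, chols = chols)
}

#' Misclassification-risk cost function G
#'
#' For every validation spectrum the risk ratio
#' `g_n = r2(x_n, m_true) / min over wrong classes r2(x_n, m_wrong)` is the
#' squared Mahalanobis distance to its own class centre divided by the
#' distance to the nearest wrong-class centre; `G` is the average of `g_n`
#' over the `NV` validation spectra. Small G means validation samples sit
#' close to their own class and far from every other: the quantity both
#' wavenumber selectors (SPA, GA) minimise. Class means and the metric are
#' estimated from the training block only.
#'
#' @param train_x,train_y Training feature matrix and labels (every class
#'   needs >= 2 samples for the pooled metric).
#' @param valid_x,valid_y Validation feature matrix and labels (non-empty).
#' @param variables Column indices to evaluate (default all).
#' @param covariance_mode `"pooled"` (one training covariance over the
#'   selected variables, default) or `"per-class"` (shrunk class
#'   covariances).
#' @return Object of class `risk_evaluation`: `gn`, `NV`, `G`, and
#'   `n_degenerate` (validation points exactly at a wrong-class centre,
#'   which get `g_n = Inf`).
#' @export
risk_G <- function(train_x, train_y, valid_x, valid_y, variables = NULL,
                   covariance_mode = c("pooled", "per-class")) {
  covariance_mode <- match.arg(covariance_mode)
  train_x <- as.matrix(train_x)
  valid_x <- as.matrix(valid_x)
  if (is.null(variables)) variables <- seq_len(ncol(train_x))
  if (!length(variables)) ftir_error("empty variable set", "config_error")
  if (!nrow(valid_x)) ftir_error("empty validation set", "config_error")

  met <- risk_metric(train_x, train_y, variables, covariance_mode)
  Vs <- valid_x[, variables, drop = FALSE]
  K <- length(met$classes)
  r2 <- matrix(NA_real_, nrow(Vs), K)
  for (k in seq_len(K)) {
    v <- backsolve(met$chols[[k]], t(Vs) - met$means[[k]], transpose = TRUE)
    r2[, k] <- colSums(v^2)
  }
  truek <- match(as.character(valid_y), met$classes)
  if (anyNA(truek)) ftir_error("validation label absent from training classes", "label_error")
  num <- r2[cbind(seq_len(nrow(Vs)), truek)]
  r2[cbind(seq_len(nrow(Vs)), truek)] <- Inf
  den <- apply(r2, 1, min)
  gn <- ifelse(den == 0, Inf, num / den)
  structure(list(gn = gn, NV = length(gn), G = mean(gn),
                 n_degenerate = sum(den == 0)),
            class = "risk_evaluation")
}
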