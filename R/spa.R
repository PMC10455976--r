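#' Successive projections algorithm wavenumber selection
#'
#' Builds, for each candidate starting wavenumber, a chain of variables in
#' which every new variable has the largest projection onto the orthogonal
#' complement of the span of the variables already chosen (so chained
#' columns are minimally collinear over the training samples). Every chain
#' prefix of length `1..max_vars` is scored with the misclassification-risk
#' cost [risk_G()] on the supplied validation block, and the (start, length)
#' combination with minimum G wins. Deterministic given its inputs.
#'
#' @param train_x,train_y Training block used both for the projection
#'   chains and the risk metric.
#' @param valid_x,valid_y Validation block scored by [risk_G()].
#' @param max_vars Longest chain to examine (>= 1, at most the number of
#'   wavenumbers; chains stop early if the residual column space is
#'   exhausted).
#' @param covariance_mode Metric for [risk_G()].
#' @param starts Optional subset of starting column indices (default: every
#'   column).
#' @return Object of class `spa_result`: `selected` (indices in chain
#'   order), `G`, `G_curve` (G versus prefix length for the winning start),
#'   `start`.
#' @export
spa_select <- function(train_x, train_y, valid_x, valid_y, max_vars,
                       covariance_mode = c("pooled", "per-class"),
                       starts = NULL) {
  covariance_mode <- match.arg(covariance_mode)
  train_x <- as.matrix(train_x)
  p <- ncol(train_x)
  if (max_vars < 1 || max_vars > p) {
    ftir_error("max_vars must lie between 1 and the number of wavenumbers",
               "config_error")
  }
  if (is.null(starts)) starts <- seq_len(p)

  best <- list(G = Inf)
  for (s in starts) {
    chain <- spa_chain(train_x, s, max_vars)
    curve <- rep(NA_real_, length(chain))
    for (len in seq_along(chain)) {
      g <- tryCatch(
        risk_G(train_x, train_y, valid_x, valid_y, chain[seq_len(len)],
               covariance_mode)$G,
        ftirqda_error = function(e) Inf)
      curve[len] <- g
      if (is.finite(g) && g < best$G) {
        best <- list(G = g, selected = chain[seq_len(len)], start = s,
                     G_curve = curve)
      }
    }
    if (identical(best$start, s)) best$G_curve <- curve
  }
  if (!is.finite(best$G)) ftir_error("no feasible SPA chain", "singularity_error")
  structure(best[c("selected", "G", "G_curve", "start")], class = "spa_result")
}

# chain of column indices by successive orthogonal projection, starting at s
spa_chain <- function(X, s, max_vars) {
  P <- X
  chain <- integer(0)
  current <- s
  for (step in seq_len(max_vars)) {
    chain <- c(chain, current)
    if (step == max_vars) break
    v <- P[, current]
    nv <- sum(v^2)
    if (nv <= 1e-12 * max(colSums(X^2))) break # residual space exhausted
    P <- P - v %*% (crossprod(v, P) / nv)
    norms <- colSums(P^2)
    norms[chain] <- -Inf
    if (max(norms) <= 1e-12 * max(colSums(X^2))) break
    current <- which.max(norms)
  }
  chain
}

#' Table of selected wavenumbers
#'
#' Maps the indices chosen by [spa_select()] or [ga_select()] to
#' wavenumbers in cm^-1, sorted descending, together with the achieved risk
#' G and the variable count.
#'
#' @param result A `spa_result` or `ga_result`.
#' @param wavenumbers The axis the indices refer to.
#' @return Data frame with columns `index` and `wavenumber`; attributes `G`
#'   and `n_vars`.
#' @export
selection_report <- function(result, wavenumbers) {
  idx <- result$selected
  if (!length(idx)) ftir_error("empty selection", "config_error")
  if (any(idx < 1 | idx > length(wavenumbers))) {
    ftir_error("selected index outside the axis", "dimension_error")
  }
  o <- order(wavenumbers[idx], decreasing = TRUE)
  out <- data.frame(index = idx[o], wavenumber = wavenumbers[idx][o])
  attr(out, "G") <- result$G
  attr(out, "n_vars") <- length(idx)
  out
}
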