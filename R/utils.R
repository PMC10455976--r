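#' @keywords internal
"_PACKAGE"

# classed error helper so callers can condition on failure mode
ftir_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("ftirqda_", class), "ftirqda_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tolerance used when matching wavenumbers to closed intervals; the grid is
# stored in floating point, so interval ends that are exact in rational
# arithmetic (e.g. 900 on the default grid) may be off by a few ulps
axis_tol <- function(wavenumbers) {
  sp <- abs(diff(wavenumbers))
  1e-6 * stats::median(sp)
}

in_closed_interval <- function(x, low, high, tol = 0) {
  x >= low - tol & x <= high + tol
}

#' The six ordered tissue classes
#'
#' Canonical class labels for the oesophageal transformation sequence, in
#' disease-stage order: normal squamous epithelium, inflammatory squamous
#' epithelium, Barrett's oesophagus, low-grade dysplasia, high-grade
#' dysplasia, oesophageal adenocarcinoma.
#'
#' @return Character vector of the six class labels.
#' @export
tissue_classes <- function() {
  c("normal", "inflammatory", "barretts", "lgd", "hgd", "oac")
}
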