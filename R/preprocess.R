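#' Preprocessing configuration
#'
#' Settings for the pre-treatment chain applied to raw absorbance spectra:
#' truncation to the biochemical fingerprint region (1800-900 cm^-1),
#' rubber-band baseline correction, and normalisation to the amide I peak
#' (1700-1600 cm^-1).
#'
#' @param cut_low,cut_high Fingerprint window in cm^-1 (closed interval).
#' @param amide_low,amide_high Amide I normalisation window in cm^-1; must
#'   lie inside the cut window.
#' @param steps Ordered subset of `c("cut", "baseline", "normalise")`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cut_low = 900, cut_high = 1800,
                              amide_low = 1600, amide_high = 1700,
                              steps = c("cut", "baseline", "normalise")) {
  if (cut_low >= cut_high) ftir_error("cut_low must be below cut_high", "config_error")
  if (amide_low < cut_low || amide_high > cut_high || amide_low >= amide_high) {
    ftir_error("amide window must lie inside the cut window", "config_error")
  }
  steps <- match.arg(steps, c("cut", "baseline", "normalise"), several.ok = TRUE)
  if (!length(steps)) ftir_error("at least one preprocessing step required", "config_error")
  structure(list(cut_low = cut_low, cut_high = cut_high,
                 amide_low = amide_low, amide_high = amide_high,
                 steps = steps),
            class = "preprocess_config")
}

#' Truncate spectra to a wavenumber interval
#'
#' Pure selection of the axis points inside the closed interval
#' `[low, high]` cm^-1; retained absorbance values are untouched. On the
#' default instrument grid (4000-600 cm^-1 at 300/78 cm^-1 spacing) the
#' 1800-900 cut retains exactly 235 wavenumbers.
#'
#' @param ds A [spectral_dataset()].
#' @param low,high Interval bounds in cm^-1.
#' @return The truncated [spectral_dataset()].
#' @export
cut_spectra <- function(ds, low = 900, high = 1800) {
  stopifnot(inherits(ds, "spectral_dataset"))
  keep <- in_closed_interval(ds$wavenumbers, low, high, axis_tol(ds$wavenumbers))
  if (!any(keep)) {
    ftir_error(sprintf("no wavenumbers inside [%g, %g] cm^-1", low, high),
               "interval_error")
  }
  spectral_dataset(ds$wavenumbers[keep],
                   ds$absorbance[, keep, drop = FALSE], ds$meta)
}

# piecewise-linear baseline through the vertices of the lower convex hull
# of (x, y), x strictly ascending (Andrew's monotone chain)
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      j <- idx[m - 1L]; k <- idx[m]
      # pop k when it lies on or above the segment j -> i
      if ((x[k] - x[j]) * (y[i] - y[j]) - (y[k] - y[j]) * (x[i] - x[j]) <= 0) {
        m <- m - 1L
      } else break
    }
    m <- m + 1L
    idx[m] <- i
  }
  hull <- idx[seq_len(m)]
  stats::approx(x[hull], y[hull], xout = x, rule = 2)$y
}

#' Rubber-band baseline correction
#'
#' Subtracts the piecewise-linear baseline running through the lower convex
#' hull of the spectrum between its two endpoints (the classical rubber-band
#' stretched under the curve). The corrected spectrum is non-negative and
#' exactly zero at both endpoints and at every hull vertex; the operation is
#' idempotent.
#'
#' @param spectrum Numeric absorbance vector (>= 3 points, finite).
#' @param wavenumbers Matching axis (either direction).
#' @return Corrected absorbance vector.
#' @export
rubber_band_baseline <- function(spectrum, wavenumbers) {
  if (length(spectrum) < 3) ftir_error("need at least 3 points", "format_error")
  if (length(spectrum) != length(wavenumbers)) {
    ftir_error("spectrum and axis lengths differ", "dimension_error")
  }
  if (any(!is.finite(spectrum))) ftir_error("non-finite absorbance", "format_error")
  o <- order(wavenumbers)
  base <- numeric(length(spectrum))
  base[o] <- lower_hull_baseline(wavenumbers[o], spectrum[o])
  spectrum - base
}

#' Normalise to the amide I peak
#'
#' Divides the spectrum by its maximum absorbance inside the amide I window
#' so the window maximum becomes exactly 1.
#'
#' @param spectrum Numeric absorbance vector.
#' @param wavenumbers Matching axis.
#' @param window Length-2 numeric, window bounds in cm^-1 (default
#'   `c(1600, 1700)`).
#' @return Normalised absorbance vector.
#' @export
normalise_amide_i <- function(spectrum, wavenumbers, window = c(1600, 1700)) {
  if (length(spectrum) != length(wavenumbers)) {
    ftir_error("spectrum and axis lengths differ", "dimension_error")
  }
  sel <- in_closed_interval(wavenumbers, min(window), max(window),
                            axis_tol(wavenumbers))
  if (!any(sel)) ftir_error("amide window contains no axis points", "interval_error")
  peak <- max(spectrum[sel])
  if (peak <= 0) {
    ftir_error("amide window maximum is not positive (degenerate spectrum)",
               "degenerate_error")
  }
  spectrum / peak
}

#' Apply the pre-treatment chain to a dataset
#'
#' Runs the configured steps (default cut -> baseline -> normalise) on every
#' spectrum. Errors from individual steps are annotated with the offending
#' record's identity.
#'
#' @param ds A [spectral_dataset()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed [spectral_dataset()].
#' @export
preprocess_pipeline <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "preprocess_config"))
  if (n_spectra(ds) == 0) ftir_error("empty dataset", "format_error")
  for (step in cfg$steps) {
    if (step == "cut") {
      ds <- cut_spectra(ds, cfg$cut_low, cfg$cut_high)
    } else {
      fun <- if (step == "baseline") {
        function(y) rubber_band_baseline(y, ds$wavenumbers)
      } else {
        function(y) normalise_amide_i(y, ds$wavenumbers,
                                      c(cfg$amide_low, cfg$amide_high))
      }
      for (i in seq_len(n_spectra(ds))) {
        ds$absorbance[i, ] <- tryCatch(fun(ds$absorbance[i, ]), error = function(e) {
          stop(errorCondition(
            sprintf("record %s/%d (%s), step '%s': %s",
                    ds$meta$specimen_id[i], ds$meta$replicate[i],
                    ds$meta$class[i], step, conditionMessage(e)),
            class = class(e)[class(e) != "simpleError"]))
        })
      }
    }
  }
  ds
}
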