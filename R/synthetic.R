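#' Default instrument wavenumber grid
#'
#' 4000 -> 600 cm^-1, descending, at 300/78 (~3.846) cm^-1 spacing:
#' 885 points, consistent with 8 cm^-1 resolution and 2x zero-filling, and
#' chosen so the 1800-900 cm^-1 fingerprint cut retains exactly 235
#' wavenumbers.
#'
#' @return Numeric vector of 885 wavenumbers.
#' @export
default_axis <- function() {
  4000 - (0:884) * (300 / 78)
}

#' Default six-band absorbance library
#'
#' Gaussian band profiles at the assigned biochemical wavenumbers: 1745
#' (lipid ester C=O), 1690 (nucleic-acid base carbonyl / ring breathing),
#' 1640 (amide I), 1540 (amide II), 1393 (methylene deformation) and 1225
#' cm^-1 (asymmetric phosphate stretch). Amide I is dominant in every class
#' so normalisation is well posed; the nucleic-acid and phosphate bands
#' carry a monotone amplitude trend across the six ordered disease stages,
#' and the normal/inflammatory pair differs only subtly.
#'
#' @return Data frame with one row per band: `centre`, `width` (Gaussian
#'   sigma, cm^-1), mean amplitude per class (`normal` .. `oac`, arbitrary
#'   absorbance), `cv` (log-scale coefficient of variation of the
#'   per-specimen amplitudes).
#' @export
default_band_library <- function() {
  data.frame(
    band = c("lipid_ester", "nucleic_acid", "amide_i", "amide_ii",
             "methylene", "phosphate"),
    centre = c(1745, 1690, 1640, 1540, 1393, 1225),
    width = c(12, 14, 18, 15, 10, 20),
    normal       = c(0.290, 0.250, 1.00, 0.550, 0.270, 0.255),
    inflammatory = c(0.285, 0.255, 1.00, 0.558, 0.275, 0.261),
    barretts     = c(0.280, 0.260, 1.00, 0.546, 0.280, 0.267),
    lgd          = c(0.275, 0.265, 1.00, 0.554, 0.285, 0.273),
    hgd          = c(0.270, 0.270, 1.00, 0.548, 0.290, 0.279),
    oac          = c(0.265, 0.275, 1.00, 0.556, 0.295, 0.285),
    cv = rep(0.02, 6),
    stringsAsFactors = FALSE)
}

#' Synthetic-spectra generator configuration
#'
#' Defaults emulate the study conditions: 109 specimens in six classes of
#' sizes 35/13/26/4/9/22, ten replicate point spectra per specimen on the
#' default 885-point grid, and a normal/inflammatory overlap of 1 (the two
#' classes' band-amplitude means coincide, reproducing the confusion
#' structure the real tissue data showed).
#'
#' @param class_sizes Named integer vector over [tissue_classes()]
#'   (a zero size omits the class).
#' @param replicates Point spectra per specimen.
#' @param axis Wavenumber grid (default [default_axis()]).
#' @param bands Band library (default [default_band_library()]).
#' @param separation Separation scale `s >= 0` applied geometrically to the
#'   between-class amplitude ratios: class mean `m = mbar * (a / mbar)^s`
#'   with `mbar` the across-class mean, so `s = 0` erases all class signal,
#'   `s = 1` reproduces the library and larger `s` widens the ratios while
#'   keeping amplitudes positive.
#' @param overlap Normal/inflammatory overlap `o` in `[0, 1]`: both class
#'   means move toward their midpoint, coinciding at `o = 1`.
#' @param baseline_sd Standard deviations of the random per-replicate
#'   baseline polynomial coefficients (offset, linear, quadratic over the
#'   axis rescaled to [-1, 1]).
#' @param gain_sd Standard deviation of the multiplicative gain
#'   `1 + epsilon` per replicate.
#' @param noise_sd Additive white-noise standard deviation (absorbance
#'   units).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   datasets.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(class_sizes = c(normal = 35, inflammatory = 13,
                                             barretts = 26, lgd = 4,
                                             hgd = 9, oac = 22),
                             replicates = 10, axis = default_axis(),
                             bands = default_band_library(),
                             separation = 5, overlap = 1,
                             baseline_sd = c(0.01, 0.01, 0.005),
                             gain_sd = 0.02, noise_sd = 0.005, seed = 1) {
  if (any(class_sizes < 0) || sum(class_sizes) < 1) {
    ftir_error("class sizes must be non-negative with at least one specimen",
               "config_error")
  }
  if (!all(names(class_sizes) %in% tissue_classes())) {
    ftir_error("class_sizes names must come from tissue_classes()", "config_error")
  }
  if (separation < 0 || overlap < 0 || overlap > 1) {
    ftir_error("need separation >= 0 and overlap in [0, 1]", "config_error")
  }
  if (any(bands$centre < min(axis)) || any(bands$centre > max(axis))) {
    ftir_error("band centre outside the wavenumber axis", "config_error")
  }
  if (gain_sd < 0 || noise_sd < 0 || any(baseline_sd < 0)) {
    ftir_error("noise standard deviations must be >= 0", "config_error")
  }
  structure(list(class_sizes = class_sizes, replicates = replicates,
                 axis = axis, bands = bands, separation = separation,
                 overlap = overlap, baseline_sd = baseline_sd,
                 gain_sd = gain_sd, noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

# effective per-class band-amplitude means after overlap and separation
effective_band_means <- function(cfg) {
  amp <- as.matrix(cfg$bands[, tissue_classes()]) # bands x classes
  if (all(c("normal", "inflammatory") %in% colnames(amp))) {
    mid <- (amp[, "normal"] + amp[, "inflammatory"]) / 2
    amp[, "normal"] <- amp[, "normal"] + cfg$overlap * (mid - amp[, "normal"])
    amp[, "inflammatory"] <- amp[, "inflammatory"] +
      cfg$overlap * (mid - amp[, "inflammatory"])
  }
  mbar <- rowMeans(amp)
  out <- mbar * (amp / mbar)^cfg$separation
  rownames(out) <- cfg$bands$band
  out
}

#' Generate a synthetic six-class ATR-FTIR dataset
#'
#' Per specimen, band amplitudes are drawn log-normally around the
#' class means (after applying the overlap and separation knobs); each
#' replicate spectrum is the sum of the Gaussian band profiles, times a
#' random multiplicative gain, plus a random slow polynomial baseline and
#' additive white noise. Specimens are emitted in randomised order.
#' Deterministic from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List with `dataset` (a [spectral_dataset()]) and `truth`
#'   (class `synthetic_truth`: per-specimen labels and true band
#'   amplitudes, the effective class band means, and the config).
#' @export
generate_spectra <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sizes <- cfg$class_sizes[cfg$class_sizes > 0]
  classes <- rep(names(sizes), sizes)
  n_spec <- length(classes)
  ord <- sample.int(n_spec)
  classes <- classes[ord]
  ids <- sprintf("spec%03d", seq_len(n_spec))

  means <- effective_band_means(cfg) # bands x classes
  nb <- nrow(cfg$bands)
  wn <- cfg$axis
  npt <- length(wn)
  profiles <- vapply(seq_len(nb), function(b) {
    exp(-(wn - cfg$bands$centre[b])^2 / (2 * cfg$bands$width[b]^2))
  }, numeric(npt)) # npt x nb
  t01 <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1

  amps <- matrix(NA_real_, n_spec, nb,
                 dimnames = list(ids, cfg$bands$band))
  total <- n_spec * cfg$replicates
  ab <- matrix(NA_real_, total, npt)
  meta <- data.frame(specimen_id = rep(ids, each = cfg$replicates),
                     replicate = rep(seq_len(cfg$replicates), n_spec),
                     class = rep(classes, each = cfg$replicates),
                     stringsAsFactors = FALSE)
  row <- 1L
  for (i in seq_len(n_spec)) {
    m <- means[, classes[i]]
    amps[i, ] <- m * exp(stats::rnorm(nb, 0, cfg$bands$cv))
    signal <- as.numeric(profiles %*% amps[i, ])
    for (r in seq_len(cfg$replicates)) {
      gain <- 1 + stats::rnorm(1, 0, cfg$gain_sd)
      bl <- stats::rnorm(3, 0, cfg$baseline_sd)
      baseline <- bl[1] + bl[2] * t01 + bl[3] * t01^2
      ab[row, ] <- gain * signal + baseline +
        stats::rnorm(npt, 0, cfg$noise_sd)
      row <- row + 1L
    }
  }
  truth <- structure(list(specimen_id = ids, class = classes,
                          amplitudes = amps, class_band_means = means,
                          config = cfg),
                     class = "synthetic_truth")
  list(dataset = spectral_dataset(wn, ab, meta), truth = truth)
}

#' How close a wavenumber selection sits to the true discriminative bands
#'
#' For each selected wavenumber, the distance in cm^-1 to the nearest
#' discriminative band centre (a band whose effective class amplitude means
#' actually differ), summarised by the median distance. Used to check that
#' SPA/GA recover the planted class signal.
#'
#' @param truth The `synthetic_truth` from [generate_spectra()].
#' @param selected Indices into the axis the selection refers to (e.g. the
#'   `selected` field of a `spa_result`/`ga_result`).
#' @param wavenumbers The axis those indices refer to (default: the
#'   generator axis; pass the cut axis when selection ran on cut spectra).
#' @return Data frame with `wavenumber`, `nearest_band`, `distance`;
#'   attribute `median_distance`.
#' @export
truth_recovery_report <- function(truth, selected, wavenumbers = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(selected)) ftir_error("empty selection", "config_error")
  wn <- wavenumbers %||% truth$config$axis
  m <- truth$class_band_means
  disc <- apply(m, 1, function(a) diff(range(a)) > 1e-10 * max(mean(a), 1e-300))
  if (!any(disc)) ftir_error("no discriminative band in the truth", "config_error")
  centres <- truth$config$bands$centre[disc]
  names(centres) <- truth$config$bands$band[disc]
  sel_wn <- wn[selected]
  nearest <- vapply(sel_wn, function(v) which.min(abs(centres - v)), integer(1))
  out <- data.frame(wavenumber = sel_wn,
                    nearest_band = names(centres)[nearest],
                    distance = abs(sel_wn - centres[nearest]))
  attr(out, "median_distance") <- stats::median(out$distance)
  out
}
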