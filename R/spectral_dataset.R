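#' Construct a labelled spectral dataset
#'
#' Container for a set of absorbance spectra sharing one wavenumber axis,
#' with per-spectrum metadata (specimen id, replicate index, tissue class).
#' The axis is stored descending (4000 -> 600 cm^-1, instrument convention);
#' an ascending axis is accepted and flipped together with the absorbance
#' columns.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone, all positive, near-uniform spacing (variation <= 1% of the
#'   median spacing).
#' @param absorbance Numeric matrix, one row per spectrum, columns aligned
#'   to `wavenumbers`. No missing values.
#' @param meta Data frame with columns `specimen_id` (character),
#'   `replicate` (integer >= 1) and `class` (one of [tissue_classes()]).
#'   `specimen_id` x `replicate` pairs must be unique.
#' @return An object of class `spectral_dataset` with elements
#'   `wavenumbers`, `absorbance` and `meta` (with `class` as a factor over
#'   all six levels).
#' @export
spectral_dataset <- function(wavenumbers, absorbance, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"

  if (length(wavenumbers) < 2) {
    ftir_error("axis needs at least two wavenumbers", "axis_error")
  }
  d <- diff(wavenumbers)
  if (any(d == 0) || !(all(d > 0) || all(d < 0))) {
    ftir_error("wavenumber axis must be strictly monotone", "axis_error")
  }
  if (any(wavenumbers <= 0)) {
    ftir_error("wavenumbers must be positive", "axis_error")
  }
  sp <- abs(d)
  if (max(abs(sp - stats::median(sp))) > 0.01 * stats::median(sp)) {
    ftir_error("wavenumber spacing varies by more than 1% (non-uniform grid)",
               "axis_error")
  }
  if (d[1] > 0) { # ascending on input: store descending
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }

  if (ncol(absorbance) != length(wavenumbers)) {
    ftir_error("absorbance columns do not match the wavenumber axis",
               "format_error")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    ftir_error("absorbance contains missing or non-finite values",
               "format_error")
  }

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("specimen_id", "replicate", "class")
  if (!all(req %in% names(meta))) {
    ftir_error("metadata must have specimen_id, replicate and class columns",
               "format_error")
  }
  if (nrow(meta) != nrow(absorbance)) {
    ftir_error("metadata rows do not match spectra", "format_error")
  }
  cls <- as.character(meta$class)
  if (anyNA(cls) || any(!nzchar(cls))) {
    ftir_error("every spectrum must carry a class label", "label_error")
  }
  bad <- setdiff(unique(cls), tissue_classes())
  if (length(bad)) {
    ftir_error(sprintf("unknown class label(s): %s (allowed: %s)",
                       paste(bad, collapse = ", "),
                       paste(tissue_classes(), collapse = ", ")),
               "label_error")
  }
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$replicate) || any(meta$replicate < 1)) {
    ftir_error("replicate indices must be integers >= 1", "format_error")
  }
  meta$class <- factor(cls, levels = tissue_classes())
  key <- paste(meta$specimen_id, meta$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    ftir_error("specimen_id x replicate pairs must be unique", "format_error")
  }
  rownames(meta) <- NULL
  dimnames(absorbance) <- NULL

  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers (%.1f..%.1f cm^-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  cat("specimens:", length(unique(x$meta$specimen_id)), "\n")
  print(table(x$meta$class))
  invisible(x)
}

n_spectra <- function(ds) nrow(ds$absorbance)

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Read a labelled spectral dataset from delimited text
#'
#' Two layouts are supported. `wide`: a CSV whose first three rows are the
#' metadata block (`specimen_id`, `replicate`, `class`, one column per
#' spectrum, first cell the row name) followed by one row per wavenumber
#' (first cell the wavenumber). `long`: a CSV with columns
#' `specimen_id,replicate,class,wavenumber,absorbance`, one row per
#' (spectrum, wavenumber) pair.
#'
#' @param path Path to the CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [spectral_dataset()]; the axis is canonicalised to descending
#'   order, spectrum order is otherwise preserved.
#' @export
read_dataset <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) ftir_error(paste("no such file:", path), "io_error")
  raw <- utils::read.csv(path, header = (layout == "long"),
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (layout == "wide") {
    if (nrow(raw) < 5 || ncol(raw) < 2) {
      ftir_error("wide file too small to hold a metadata block and an axis",
                 "format_error")
    }
    labels <- raw[[1]][1:3]
    if (!identical(tolower(labels), c("specimen_id", "replicate", "class"))) {
      ftir_error("wide layout must start with specimen_id/replicate/class rows",
                 "format_error")
    }
    meta <- data.frame(specimen_id = as.character(raw[1, -1]),
                       replicate = as.character(raw[2, -1]),
                       class = as.character(raw[3, -1]),
                       stringsAsFactors = FALSE)
    if (anyNA(meta$class) || any(!nzchar(meta$class))) {
      ftir_error("missing class label in wide header block", "label_error")
    }
    body <- raw[-(1:3), , drop = FALSE]
    wn <- suppressWarnings(as.numeric(body[[1]]))
    vals <- suppressWarnings(vapply(body[-1], as.numeric, numeric(nrow(body))))
    if (anyNA(wn) || anyNA(vals)) {
      ftir_error("non-numeric wavenumber or absorbance entries", "format_error")
    }
    spectral_dataset(wn, t(vals), meta)
  } else {
    req <- c("specimen_id", "replicate", "class", "wavenumber", "absorbance")
    if (!all(req %in% names(raw))) {
      ftir_error("long layout needs columns specimen_id,replicate,class,wavenumber,absorbance",
                 "format_error")
    }
    wn_all <- suppressWarnings(as.numeric(raw$wavenumber))
    ab_all <- suppressWarnings(as.numeric(raw$absorbance))
    if (anyNA(wn_all) || anyNA(ab_all)) {
      ftir_error("non-numeric wavenumber or absorbance entries", "format_error")
    }
    key <- paste(raw$specimen_id, raw$replicate, sep = "\r")
    first <- !duplicated(key)
    keys <- key[first]
    wn <- wn_all[key == keys[1]]
    n <- length(wn)
    ab <- matrix(NA_real_, length(keys), n)
    for (i in seq_along(keys)) {
      sel <- key == keys[i]
      if (sum(sel) != n || any(wn_all[sel] != wn)) {
        ftir_error("spectra in long file do not share one wavenumber axis",
                   "format_error")
      }
      ab[i, ] <- ab_all[sel]
    }
    meta <- data.frame(specimen_id = raw$specimen_id[first],
                       replicate = raw$replicate[first],
                       class = raw$class[first],
                       stringsAsFactors = FALSE)
    spectral_dataset(wn, ab, meta)
  }
}

#' Write a labelled spectral dataset to delimited text
#'
#' Inverse of [read_dataset()]; numbers are written with 12 significant
#' digits so a round trip reproduces the dataset to well below 1e-9.
#'
#' @param ds A [spectral_dataset()].
#' @param path Output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(ds, "spectral_dataset"))
  if (n_spectra(ds) == 0) ftir_error("dataset holds no spectra", "format_error")
  if (layout == "wide") {
    header <- rbind(c("specimen_id", ds$meta$specimen_id),
                    c("replicate", as.character(ds$meta$replicate)),
                    c("class", as.character(ds$meta$class)))
    abch <- matrix(fmt_num(ds$absorbance), nrow = nrow(ds$absorbance))
    body <- cbind(fmt_num(ds$wavenumbers), t(abch))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(apply(rbind(header, body), 1, paste, collapse = ","), con)
  } else {
    n <- length(ds$wavenumbers)
    m <- n_spectra(ds)
    df <- data.frame(
      specimen_id = rep(ds$meta$specimen_id, each = n),
      replicate = rep(ds$meta$replicate, each = n),
      class = rep(as.character(ds$meta$class), each = n),
      wavenumber = rep(fmt_num(ds$wavenumbers), times = m),
      absorbance = fmt_num(as.vector(t(ds$absorbance))),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Average replicate spectra per specimen
#'
#' Point spectra are acquired from several random locations per specimen;
#' modelling is per specimen by default, so replicates are collapsed to
#' their arithmetic mean before fitting. Idempotent.
#'
#' @param ds A [spectral_dataset()].
#' @return A [spectral_dataset()] with one record per specimen
#'   (`replicate = 1`), specimens in first-appearance order.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  ids <- unique(ds$meta$specimen_id)
  ab <- matrix(NA_real_, length(ids), length(ds$wavenumbers))
  cls <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- ds$meta$specimen_id == ids[i]
    ck <- unique(as.character(ds$meta$class[sel]))
    if (length(ck) > 1) {
      ftir_error(sprintf("specimen %s carries conflicting class labels (%s)",
                         ids[i], paste(ck, collapse = ", ")), "label_error")
    }
    cls[i] <- ck
    ab[i, ] <- colMeans(ds$absorbance[sel, , drop = FALSE])
  }
  spectral_dataset(ds$wavenumbers, ab,
                   data.frame(specimen_id = ids, replicate = 1L, class = cls,
                              stringsAsFactors = FALSE))
}

#' Specimens per tissue class
#'
#' @param ds A [spectral_dataset()].
#' @return Named integer vector over all six classes (zeros included),
#'   counting distinct specimens.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  first <- !duplicated(ds$meta$specimen_id)
  tab <- table(ds$meta$class[first])
  out <- as.integer(tab[tissue_classes()])
  names(out) <- tissue_classes()
  out[is.na(out)] <- 0L
  out
}
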