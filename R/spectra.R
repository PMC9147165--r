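#' Spectra container
#'
#' An aligned block of absorbance spectra sharing one acquisition technique
#' and one nominal resolution. The container holds the wavenumber axis
#' (strictly increasing, uniformly spaced), an `n x p` absorbance matrix
#' (one row per recorded spectrum) and a per-row metadata tibble with
#' columns `sample_id`, `technique` (`"ATR"` or `"TRANS"`), `resolution`
#' (2, 4 or 8 cm^-1) and `replicate` (1..3).
#'
#' Axis coverage follows the two acquisition modes: attenuated total
#' reflectance (ATR) spectra live within 500--4000 cm^-1, transmission
#' (TRANS) spectra within 600--4000 cm^-1.
#'
#' @param axis Numeric vector of wavenumbers (cm^-1). May be descending;
#'   it is stored ascending and the value columns are reordered to match.
#' @param values Numeric matrix, `n` spectra by `length(axis)` points.
#' @param meta Data frame with columns `sample_id`, `technique`,
#'   `resolution`, `replicate`; one row per spectrum.
#' @return A `spectra` object.
#' @examples
#' ax <- seq(600, 4000, by = 4)
#' m <- matrix(rnorm(2 * length(ax), 0.5, 0.01), 2)
#' sp <- spectra(ax, m, tibble::tibble(
#'   sample_id = c("s1", "s1"), technique = "TRANS",
#'   resolution = 8, replicate = 1:2
#' ))
#' sp
#' @export
spectra <- function(axis, values, meta) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  meta <- as_tibble(meta)
  if (length(axis) > 1 && is.unsorted(axis)) {
    ord <- order(axis)
    axis <- axis[ord]
    values <- values[, ord, drop = FALSE]
  }
  out <- structure(
    list(axis = as.numeric(axis), values = unname(values), meta = meta),
    class = "spectra"
  )
  validate_spectra(out)
}

validate_spectra <- function(x) {
  p <- length(x$axis)
  if (ncol(x$values) != p) {
    abort("`values` must have one column per axis point")
  }
  if (nrow(x$values) != nrow(x$meta)) {
    abort("`meta` must have one row per spectrum")
  }
  if (anyNA(x$values) || any(!is.finite(x$values))) {
    abort("absorbance values must be finite and non-missing")
  }
  axis_spacing(x$axis)
  need <- c("sample_id", "technique", "resolution", "replicate")
  miss <- setdiff(need, names(x$meta))
  if (length(miss)) {
    abort(paste0("meta is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x$meta) > 0) {
    if (length(unique(x$meta$technique)) > 1 ||
        length(unique(x$meta$resolution)) > 1) {
      abort("inconsistent metadata: all rows must share one technique and one resolution",
            class = "oilspec_inconsistent_meta")
    }
    tech <- x$meta$technique[1]
    if (!tech %in% c("ATR", "TRANS")) {
      abort('technique must be "ATR" or "TRANS"')
    }
    if (!x$meta$resolution[1] %in% c(2, 4, 8)) {
      abort("resolution must be 2, 4 or 8 cm^-1")
    }
    if (any(!x$meta$replicate %in% 1:3)) {
      abort("replicate must be 1, 2 or 3")
    }
    lo <- if (tech == "ATR") 500 else 600
    if (p > 0 && (x$axis[1] < lo - 1e-9 || x$axis[p] > 4000 + 1e-9)) {
      abort(sprintf("%s axis must lie within [%d, 4000] cm^-1", tech, lo))
    }
  }
  x
}

#' @export
print.spectra <- function(x, ...) {
  p <- length(x$axis)
  cat(sprintf(
    "<spectra: %d spectra x %d points, %s R%s, %.6g-%.6g cm^-1>\n",
    nrow(x$values), p,
    if (nrow(x$meta)) x$meta$technique[1] else "?",
    if (nrow(x$meta)) x$meta$resolution[1] else "?",
    if (p) x$axis[1] else NA, if (p) x$axis[p] else NA
  ))
  invisible(x)
}

#' @export
dim.spectra <- function(x) dim(x$values)

#' Convert spectra to a long tibble
#'
#' One row per (spectrum, wavenumber) pair; convenient for ggplot2.
#'
#' @param x A [spectra] object.
#' @param ... Unused.
#' @return A tibble with metadata columns plus `wavenumber` and `absorbance`.
#' @export
as_tibble.spectra <- function(x, ...) {
  n <- nrow(x$values)
  p <- length(x$axis)
  out <- x$meta[rep(seq_len(n), each = p), , drop = FALSE]
  out$wavenumber <- rep(x$axis, times = n)
  out$absorbance <- as.vector(t(x$values))
  as_tibble(out)
}

spectrum_column_names <- function(meta) {
  sprintf("%s|%s|R%d|rep%d", meta$sample_id, meta$technique,
          as.integer(meta$resolution), as.integer(meta$replicate))
}

parse_spectrum_column_names <- function(nms) {
  parts <- strsplit(nms, "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    abort(paste0("cannot parse spectrum column name(s): ",
                 paste(nms[bad], collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  res <- suppressWarnings(as.integer(sub("^R", "", m[, 3])))
  rep_ <- suppressWarnings(as.integer(sub("^rep", "", m[, 4])))
  if (anyNA(res) || anyNA(rep_)) {
    abort("spectrum column names must encode R<resolution> and rep<k>")
  }
  tibble(sample_id = m[, 1], technique = m[, 2],
         resolution = res, replicate = rep_)
}

#' Read a wide-format spectra CSV
#'
#' The file carries the wavenumber axis in its first column
#' (`wavenumber_cm-1`) and one column per recorded spectrum, named
#' `<sample_id>|<technique>|R<resolution>|rep<k>`. A descending axis is
#' accepted and normalised to ascending order.
#'
#' @param path Path to the CSV file.
#' @return A [spectra] object; spectra appear in file column order.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1) {
    abort("spectra CSV must contain at least a wavenumber column")
  }
  df <- lapply(seq_along(raw), function(j) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value at row %d, column %s of %s",
                    bad[1], names(raw)[j], path))
    }
    v
  })
  names(df) <- names(raw)
  axis <- df[[1]]
  if (length(df) == 1) {
    return(spectra(axis, matrix(numeric(0), 0, length(axis)),
                   tibble(sample_id = character(), technique = character(),
                          resolution = integer(), replicate = integer())))
  }
  meta <- parse_spectrum_column_names(names(df)[-1])
  values <- t(do.call(cbind, df[-1]))
  spectra(axis, values, meta)
}

#' Write spectra to a wide-format CSV
#'
#' Inverse of [read_spectra_csv()]: values survive a write/read round trip
#' bit-exactly (shortest round-trippable decimal representation).
#'
#' @param x A [spectra] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  validate_spectra(x)
  # 17 significant digits round-trip IEEE doubles exactly
  df <- c(list(sprintf("%.17g", x$axis)),
          lapply(seq_len(nrow(x$values)),
                 function(i) sprintf("%.17g", x$values[i, ])))
  names(df) <- c("wavenumber_cm-1", spectrum_column_names(x$meta))
  readr::write_csv(as_tibble(df, .name_repair = "minimal"), path,
                   progress = FALSE)
  invisible(path)
}

#' Average replicate spectra per sample
#'
#' Replaces the (up to three) replicate spectra of each sample by their
#' unweighted arithmetic mean. Output rows follow the order in which each
#' sample first appears; the replicate index is reset to 1.
#'
#' @param x A [spectra] object.
#' @return A [spectra] object with one row per `sample_id`.
#' @export
average_replicates <- function(x) {
  ids <- unique(x$meta$sample_id)
  rows <- lapply(ids, function(id) {
    idx <- which(x$meta$sample_id == id)
    colMeans(x$values[idx, , drop = FALSE])
  })
  meta <- x$meta[match(ids, x$meta$sample_id), , drop = FALSE]
  meta$replicate <- 1L
  spectra(x$axis, do.call(rbind, rows), meta)
}

#' Check axis spacing against the nominal resolution
#'
#' FT-IR instruments typically store spectra at a point spacing of half the
#' nominal resolution; some software interpolates to the resolution itself.
#' Both conventions are accepted, each within a 50% relative tolerance.
#'
#' @param x A [spectra] object.
#' @return `TRUE` if the axis spacing is consistent with the nominal
#'   resolution of the block, `FALSE` otherwise.
#' @export
validate_resolution <- function(x) {
  if (length(x$axis) < 2 || nrow(x$meta) == 0) {
    return(FALSE)
  }
  h <- axis_spacing(x$axis)
  res <- x$meta$resolution[1]
  isTRUE(abs(h - res) <= 0.5 * res) || isTRUE(abs(h - res / 2) <= 0.25 * res)
}

#' Plot spectra
#'
#' @param object A [spectra] object.
#' @param ... Unused.
#' @return A ggplot object: absorbance versus wavenumber, one line per
#'   spectrum, coloured by sample.
#' @export
autoplot.spectra <- function(object, ...) {
  df <- as_tibble(object)
  df$spectrum <- interaction(df$sample_id, df$replicate)
  ggplot(df, aes(x = .data$wavenumber, y = .data$absorbance,
                 group = .data$spectrum, colour = .data$sample_id)) +
    geom_line(linewidth = 0.3, alpha = 0.8) +
    scale_x_reverse() +
    labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (a.u.)",
         colour = "Sample") +
    theme_minimal()
}
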