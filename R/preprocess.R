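#' Preprocessing variants
#'
#' Sixteen variants are supported: five base transforms (raw spectra `RAW`,
#' unit-norm normalization `NOR`, standard normal variate `SNV`, Haar
#' wavelet approximation `WA` and detail `WD` coefficients), each followed
#' by a derivative of order 0, 1 or 2, plus the `RANDOM` control that
#' replaces the feature matrix by seeded standard-normal noise of the same
#' shape. Derivatives of the `RANDOM` control are not defined.
#'
#' String codes: `RAW`, `D1`, `D2`, `NOR`, `NOR+D1`, `NOR+D2`, `SNV`,
#' `SNV+D1`, `SNV+D2`, `WA`, `WA+D1`, `WA+D2`, `WD`, `WD+D1`, `WD+D2`,
#' `RANDOM` (`D1` is shorthand for the first derivative of the raw
#' spectra).
#'
#' @param base One of `"RAW"`, `"NOR"`, `"SNV"`, `"WA"`, `"WD"`, `"RANDOM"`.
#' @param derivative Derivative order 0, 1 or 2.
#' @return `preprocess_spec()`: a spec object. `preprocess_variants()`: the
#'   16 valid codes, in report order.
#' @export
preprocess_spec <- function(base = "RAW", derivative = 0) {
  base <- match.arg(base, c("RAW", "NOR", "SNV", "WA", "WD", "RANDOM"))
  if (!derivative %in% 0:2) {
    abort("`derivative` must be 0, 1 or 2")
  }
  if (base == "RANDOM" && derivative > 0) {
    abort("the RANDOM control replaces the whole feature matrix; derivatives of it are not defined")
  }
  structure(list(base = base, derivative = as.integer(derivative)),
            class = "preprocess_spec")
}

#' @rdname preprocess_spec
#' @export
preprocess_variants <- function() {
  c("RAW", "D1", "D2",
    "NOR", "NOR+D1", "NOR+D2",
    "SNV", "SNV+D1", "SNV+D2",
    "WA", "WA+D1", "WA+D2",
    "WD", "WD+D1", "WD+D2",
    "RANDOM")
}

#' @rdname preprocess_spec
#' @param code A string code such as `"SNV+D1"`.
#' @export
parse_preprocess <- function(code) {
  if (inherits(code, "preprocess_spec")) {
    return(code)
  }
  if (!code %in% preprocess_variants()) {
    abort(sprintf("unknown preprocessing code: %s", code))
  }
  if (code == "RANDOM") {
    return(preprocess_spec("RANDOM", 0))
  }
  parts <- strsplit(code, "+", fixed = TRUE)[[1]]
  if (parts[1] %in% c("D1", "D2")) {
    return(preprocess_spec("RAW", as.integer(sub("D", "", parts[1]))))
  }
  d <- if (length(parts) == 2) as.integer(sub("D", "", parts[2])) else 0L
  preprocess_spec(parts[1], d)
}

format_preprocess <- function(spec) {
  spec <- parse_preprocess(spec)
  if (spec$base == "RANDOM") {
    return("RANDOM")
  }
  if (spec$base == "RAW") {
    return(c("RAW", "D1", "D2")[spec$derivative + 1])
  }
  if (spec$derivative == 0) spec$base else sprintf("%s+D%d", spec$base, spec$derivative)
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess:", format_preprocess(x), ">\n")
  invisible(x)
}

#' Row-wise preprocessing primitives
#'
#' `normalize_row()` scales a spectrum to unit Euclidean norm;
#' `snv_row()` applies the standard normal variate transform (centre to
#' mean 0, scale to unit standard deviation with the n-1 denominator),
#' which removes additive offsets and multiplicative scatter;
#' `derivative_row()` takes first differences on a uniform wavenumber grid
#' (applied twice for the second derivative), returning values on the
#' midpoint axis; `haar_row()` performs a single-level orthonormal Haar
#' transform, returning approximation (pairwise scaled sums) and detail
#' (pairwise scaled differences) coefficients. Odd-length rows are extended
#' by repeating the last point before the Haar pairing.
#'
#' @param x Numeric vector (one spectrum).
#' @return `normalize_row()`, `snv_row()`: numeric vector of the same
#'   length. `derivative_row()`: list with `values` and `axis`.
#'   `haar_row()`: list with `approx`, `detail` and the midpoint `axis`.
#' @examples
#' normalize_row(c(3, 4))
#' snv_row(c(1, 2, 3))
#' derivative_row(c(1, 3, 6), axis = 1:3, order = 1)
#' haar_row(c(4, 2, 6, 8))
#' @export
normalize_row <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) {
    abort("degenerate spectrum: all-zero row cannot be normalized",
          class = "oilspec_degenerate")
  }
  x / nrm
}

#' @rdname normalize_row
#' @export
snv_row <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("degenerate spectrum: constant row has no standard normal variate",
          class = "oilspec_degenerate")
  }
  (x - mean(x)) / s
}

#' @rdname normalize_row
#' @param axis Uniformly spaced wavenumber axis matching `x`.
#' @param order Derivative order, 1 or 2.
#' @export
derivative_row <- function(x, axis, order = 1) {
  if (!order %in% 1:2) {
    abort("`order` must be 1 or 2")
  }
  if (length(x) < order + 1) {
    abort("spectrum too short for the requested derivative order")
  }
  h <- axis_spacing(axis)
  for (i in seq_len(order)) {
    x <- diff(x) / h
    axis <- (axis[-1] + axis[-length(axis)]) / 2
  }
  list(values = x, axis = axis)
}

#' @rdname normalize_row
#' @export
haar_row <- function(x) {
  p <- length(x)
  if (p < 2) {
    abort("Haar transform requires at least 2 points")
  }
  if (p %% 2 == 1) {
    x <- c(x, x[p])
    p <- p + 1
  }
  odd <- seq(1, p, by = 2)
  list(approx = (x[odd] + x[odd + 1]) / sqrt(2),
       detail = (x[odd] - x[odd + 1]) / sqrt(2))
}

# Effective wavenumbers of single-level Haar coefficients: the midpoint of
# each pair on the continued uniform grid (the padded point of an
# odd-length row is treated as sitting at the next grid position, keeping
# the coefficient axis uniform so derivatives remain well defined).
haar_axis <- function(axis) {
  h <- axis_spacing(axis)
  seq(from = axis[1] + h / 2, by = 2 * h, length.out = ceiling(length(axis) / 2))
}

#' Feature matrix
#'
#' The output of preprocessing: an `n x q` matrix of model features, the
#' effective wavenumber of each column (midpoints for derivative and
#' wavelet features) and the preprocessing code that produced it.
#'
#' @param values Numeric `n x q` matrix.
#' @param axis Effective wavenumbers, strictly increasing, length `q`.
#' @param spec Preprocessing provenance (code or [preprocess_spec()]).
#' @return A `features` object.
#' @export
features <- function(values, axis, spec = "RAW") {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (length(axis) != ncol(values)) {
    abort("`axis` must have one entry per feature column")
  }
  if (length(axis) > 1 && any(diff(axis) <= 0)) {
    abort("feature axis must be strictly increasing")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("feature values must be finite")
  }
  structure(list(values = unname(values), axis = as.numeric(axis),
                 spec = format_preprocess(spec)),
            class = "features")
}

#' @export
print.features <- function(x, ...) {
  cat(sprintf("<features: %d x %d, %s>\n", nrow(x$values), ncol(x$values), x$spec))
  invisible(x)
}

#' @export
dim.features <- function(x) dim(x$values)

#' Random-feature control matrix
#'
#' Replaces spectral features by i.i.d. standard-normal draws of the same
#' shape -- a null control: a calibration pipeline must not find
#' generalizable structure in it.
#'
#' @param n,q Matrix dimensions.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param axis Optional effective axis to carry (defaults to `1:q`).
#' @return A `features` object with provenance `RANDOM`.
#' @export
random_features <- function(n, q, seed, axis = seq_len(q)) {
  n <- stopifnot_scalar_int(n, "n")
  q <- stopifnot_scalar_int(q, "q")
  if (n < 1 || q < 1) {
    abort("`n` and `q` must be at least 1")
  }
  vals <- with_seed(stopifnot_scalar_int(seed, "seed"),
                    matrix(rnorm(n * q), n, q))
  features(vals, axis, "RANDOM")
}

#' Apply a preprocessing variant to a spectra block
#'
#' The base transform (`NOR`, `SNV`, `WA`, `WD`, or none) is applied row
#' by row, then the requested finite-difference derivative is taken on the
#' transformed rows; the order matters and is fixed as base-then-derivative
#' (the first derivative of normalized spectra, not the normalization of a
#' derivative). The `RANDOM` control ignores the absorbance values and
#' returns seeded noise of the same shape.
#'
#' @param x A [spectra] object.
#' @param spec A code from [preprocess_variants()] or a [preprocess_spec()].
#' @param seed Seed for the `RANDOM` control (ignored otherwise).
#' @return A [features] object.
#' @export
apply_preprocess <- function(x, spec, seed = 1L) {
  spec <- parse_preprocess(spec)
  V <- x$values
  axis <- x$axis
  n <- nrow(V)

  if (spec$base == "RANDOM") {
    return(random_features(n, ncol(V), seed, axis = axis))
  }

  annotate <- function(expr, i) {
    tryCatch(expr, oilspec_degenerate = function(e) {
      abort(sprintf("%s (sample_id %s)", conditionMessage(e),
                    x$meta$sample_id[i]), class = "oilspec_degenerate")
    })
  }

  if (spec$base == "NOR") {
    nrm <- sqrt(rowSums(V^2))
    for (i in which(nrm == 0)) annotate(normalize_row(V[i, ]), i)
    V <- V / nrm
  } else if (spec$base == "SNV") {
    mu <- rowMeans(V)
    s <- sqrt(rowSums((V - mu)^2) / (ncol(V) - 1))
    for (i in which(s == 0 | !is.finite(s))) annotate(snv_row(V[i, ]), i)
    V <- (V - mu) / s
  } else if (spec$base %in% c("WA", "WD")) {
    p <- ncol(V)
    if (p %% 2 == 1) {
      V <- cbind(V, V[, p, drop = FALSE])
      p <- p + 1
    }
    odd <- seq(1, p, by = 2)
    V <- if (spec$base == "WA") {
      (V[, odd, drop = FALSE] + V[, odd + 1, drop = FALSE]) / sqrt(2)
    } else {
      (V[, odd, drop = FALSE] - V[, odd + 1, drop = FALSE]) / sqrt(2)
    }
    axis <- haar_axis(axis)
  }

  if (spec$derivative > 0) {
    h <- axis_spacing(axis)
    for (d in seq_len(spec$derivative)) {
      p <- ncol(V)
      V <- (V[, -1, drop = FALSE] - V[, -p, drop = FALSE]) / h
      axis <- (axis[-1] + axis[-length(axis)]) / 2
    }
  }

  features(V, axis, spec)
}
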