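#' Variable-selection specification
#'
#' Spectra carry far more wavenumbers than a calibration on ~30 samples can
#' support; before the PLS fit the feature set is reduced to a fraction
#' (40% by default) by one of three strategies: largest across-sample
#' standard deviation (`STD`), largest absolute Pearson correlation with
#' the response (`CORR`), or membership in chemically informative
#' wavenumber windows (`CHEM`). The default windows cover the fingerprint
#' region and the C=O, C-H and O-H stretch bands: 600--1500, 1600--1800,
#' 2850--3050 and 3400--3500 cm^-1.
#'
#' @param method `"STD"`, `"CORR"` or `"CHEM"`.
#' @param fraction Fraction of columns to retain for `STD`/`CORR`
#'   (0 < fraction <= 1).
#' @param chem_windows List of closed `[lo, hi]` wavenumber intervals,
#'   non-overlapping and increasing.
#' @return A `selection_spec` object.
#' @export
selection_spec <- function(method = c("STD", "CORR", "CHEM"), fraction = 0.4,
                           chem_windows = default_chem_windows()) {
  method <- match.arg(method)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1]")
  }
  win <- do.call(rbind, lapply(chem_windows, as.numeric))
  if (is.null(win) || ncol(win) != 2 || any(win[, 1] >= win[, 2])) {
    abort("`chem_windows` must be a list of [lo, hi] intervals with lo < hi")
  }
  if (nrow(win) > 1 && any(win[-1, 1] <= win[-nrow(win), 2])) {
    abort("`chem_windows` must be non-overlapping and increasing")
  }
  structure(list(method = method, fraction = fraction,
                 chem_windows = lapply(seq_len(nrow(win)), function(i) win[i, ])),
            class = "selection_spec")
}

#' @rdname selection_spec
#' @export
default_chem_windows <- function() {
  list(c(600, 1500), c(1600, 1800), c(2850, 3050), c(3400, 3500))
}

new_selection <- function(indices, spec) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) {
    abort("empty selection", class = "oilspec_empty_selection")
  }
  structure(list(indices = indices, spec = spec), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection: %d columns by %s>\n", length(x$indices),
              x$spec$method))
  invisible(x)
}

n_selected <- function(fraction, q) {
  max(1L, as.integer(round_half_up(fraction * q)))
}

# Rank columns by a score, largest first, ties broken by lower column
# index (lower wavenumber) for reproducibility.
top_k_by_score <- function(score, k) {
  sort(order(-score, seq_along(score))[seq_len(k)])
}

#' Select features for calibration
#'
#' `select_by_std()` keeps the `round(fraction * q)` columns with the
#' largest across-sample standard deviation; `select_by_corr()` keeps those
#' with the largest absolute Pearson correlation with the response;
#' `select_by_chem()` keeps every column whose effective wavenumber falls
#' inside one of the closed chemically informative windows. To avoid
#' leaking validation information into the model, `STD` and `CORR`
#' statistics must be computed on calibration rows only: pass a [features]
#' object restricted to the calibration rows.
#'
#' @param f_cal A [features] object containing calibration rows only.
#' @param fraction Fraction of columns to keep (default 0.4).
#' @return A `selection` object with sorted unique column `indices`.
#' @examples
#' f <- features(matrix(rnorm(50), 5), axis = 1:10)
#' select_by_std(f, 0.4)
#' @export
select_by_std <- function(f_cal, fraction = 0.4) {
  if (nrow(f_cal$values) < 2) {
    abort("standard-deviation selection needs at least 2 calibration rows")
  }
  spec <- selection_spec("STD", fraction)
  score <- col_sds(f_cal$values)
  new_selection(top_k_by_score(score, n_selected(fraction, ncol(f_cal$values))),
                spec)
}

#' @rdname select_by_std
#' @param y_cal Response values for the calibration rows.
#' @export
select_by_corr <- function(f_cal, y_cal, fraction = 0.4) {
  if (nrow(f_cal$values) < 3) {
    abort("correlation selection needs at least 3 calibration rows")
  }
  if (length(y_cal) != nrow(f_cal$values)) {
    abort("`y_cal` must have one value per calibration row")
  }
  if (sd(y_cal) == 0) {
    abort("uninformative response: y is constant on the calibration set")
  }
  spec <- selection_spec("CORR", fraction)
  r <- suppressWarnings(as.vector(cor(f_cal$values, y_cal)))
  r[!is.finite(r)] <- 0  # zero-variance columns carry no correlation
  new_selection(top_k_by_score(abs(r), n_selected(fraction, ncol(f_cal$values))),
                spec)
}

#' @rdname select_by_std
#' @param feature_axis Effective wavenumbers of the feature columns.
#' @param chem_windows Closed wavenumber intervals (see [selection_spec()]).
#' @export
select_by_chem <- function(feature_axis, chem_windows = default_chem_windows()) {
  if (length(feature_axis) == 0) {
    abort("feature axis is empty")
  }
  spec <- selection_spec("CHEM", chem_windows = chem_windows)
  keep <- rep(FALSE, length(feature_axis))
  for (w in spec$chem_windows) {
    keep <- keep | (feature_axis >= w[1] & feature_axis <= w[2])
  }
  if (!any(keep)) {
    abort("empty selection: no feature lies inside a chemical window",
          class = "oilspec_empty_selection")
  }
  new_selection(which(keep), spec)
}

#' Subset a feature matrix by a selection
#'
#' @param f A [features] object (calibration or validation rows).
#' @param sel A `selection` from one of the `select_by_*()` functions.
#' @return A [features] object restricted to the selected columns.
#' @export
apply_selection <- function(f, sel) {
  idx <- sel$indices
  if (any(idx < 1 | idx > ncol(f$values))) {
    abort("selection indices out of range for this feature matrix")
  }
  features(f$values[, idx, drop = FALSE], f$axis[idx], f$spec)
}
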