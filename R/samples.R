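#' Names of the thirteen dependent variables
#'
#' Six fatty acids (percent of total fatty acids), unsaponifiable matter
#' (percent), and six pharmacopoeial quality indices in their conventional
#' units (acid, saponification, ester and hydroxyl value in mg KOH/g;
#' iodine value in g I2/100 g; peroxide value in mEq O2/kg).
#'
#' @return Character vector of length 13.
#' @export
oil_responses <- function() {
  c("palmitic", "linoleic", "alpha_linolenic", "oleic", "elaidic", "stearic",
    "unsaponifiable_matter", "acid_value", "saponification_value",
    "ester_value", "hydroxyl_value", "iodine_value", "peroxide_value")
}

fatty_acid_responses <- function() {
  c("palmitic", "linoleic", "alpha_linolenic", "oleic", "elaidic", "stearic")
}

#' Validate a sample table
#'
#' A sample table has one row per oil sample: `sample_id`, `oil_type`, the
#' 13 dependent variables of [oil_responses()], and optionally a `split`
#' column (`"calibration"` or `"validation"`).
#'
#' @param samples A data frame.
#' @param require_split Require the `split` column to be present and valid?
#' @return The table as a tibble, invisibly validated.
#' @export
validate_samples <- function(samples, require_split = FALSE) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) {
    abort("sample table is empty")
  }
  need <- c("sample_id", "oil_type", oil_responses())
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("sample table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id values must be unique")
  }
  y <- as.matrix(samples[, oil_responses()])
  if (anyNA(y) || any(!is.finite(y)) || any(y < 0)) {
    abort("all dependent variables must be finite and non-negative")
  }
  fa <- as.matrix(samples[, fatty_acid_responses()])
  if (any(fa > 100)) {
    abort("fatty-acid percentages must lie in [0, 100]")
  }
  if (require_split) {
    if (!"split" %in% names(samples) ||
        any(!samples$split %in% c("calibration", "validation"))) {
      abort('`split` must be "calibration" or "validation" for every sample')
    }
    ncal <- tapply(samples$split == "calibration", samples$oil_type, sum)
    if (any(ncal < 1 | ncal > 2)) {
      abort("each oil type must have 1 or 2 calibration samples")
    }
  }
  samples
}

#' Read / write a sample table CSV
#'
#' Columns: `sample_id, oil_type`, the 13 dependent variables of
#' [oil_responses()], and optionally `split`.
#'
#' @param path CSV path.
#' @return A validated sample tibble.
#' @export
read_samples_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(df, require_split = "split" %in% names(df))
}

#' @rdname read_samples_csv
#' @param samples A sample tibble.
#' @export
write_samples_csv <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Assign samples to calibration and validation sets
#'
#' Oil types with one or two samples contribute all of them to the
#' calibration set. For types with three or more samples, two are kept as
#' calibration representatives and the rest go to validation. Validation
#' members are drawn uniformly at random -- but samples holding the global
#' minimum or maximum of any dependent variable are kept in calibration
#' where possible, so the calibration set spans the full range of every
#' response. If excluding extreme holders leaves too few candidates, the
#' draw falls back to all samples of the type.
#'
#' @param samples Sample tibble without (or ignoring) a `split` column.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return The sample tibble with a `split` column added.
#' @examples
#' tbl <- simulate_oil_dataset(synthetic_config(seed = 1))$samples
#' tbl <- assign_split(tbl, seed = 42)
#' table(tbl$split)
#' @export
assign_split <- function(samples, seed) {
  seed <- stopifnot_scalar_int(seed, "seed")
  samples <- validate_samples(samples)
  y <- as.matrix(samples[, oil_responses()])
  extreme <- rep(FALSE, nrow(samples))
  for (j in seq_len(ncol(y))) {
    extreme <- extreme | y[, j] == min(y[, j]) | y[, j] == max(y[, j])
  }
  split <- rep("calibration", nrow(samples))
  with_seed(seed, {
    for (type in unique(samples$oil_type)) {
      idx <- which(samples$oil_type == type)
      n <- length(idx)
      if (n <= 2) next
      n_val <- n - 2
      eligible <- idx[!extreme[idx]]
      pool <- if (length(eligible) >= n_val) eligible else idx
      val <- pool[sample.int(length(pool), n_val)]
      split[val] <- "validation"
    }
  })
  samples$split <- split
  validate_samples(samples, require_split = TRUE)
}
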