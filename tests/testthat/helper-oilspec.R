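# Shared fixtures, all built in code.

# A valid spectra block on a short TRANS axis.
toy_spectra <- function(values, axis = NULL, technique = "TRANS",
                        resolution = 8, sample_id = NULL, replicate = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (is.null(axis)) axis <- seq(600, by = 4, length.out = ncol(values))
  n <- nrow(values)
  spectra(axis, values, tibble::tibble(
    sample_id = sample_id %||% paste0("s", seq_len(n)),
    technique = technique, resolution = resolution,
    replicate = replicate %||% rep(1L, n)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent least-squares oracle: Moore-Penrose pseudoinverse via SVD.
svd_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

# A sample table with given per-type counts and smooth, non-degenerate
# reference values.
toy_samples <- function(type_counts, seed = 1) {
  n <- sum(type_counts)
  withr_seed <- function(code) { set.seed(seed); code }
  y <- withr_seed(matrix(runif(n * 13, 1, 99), n))
  colnames(y) <- oil_responses()
  tibble::as_tibble(y) |>
    dplyr::mutate(
      sample_id = sprintf("T%02d", seq_len(n)),
      oil_type = rep(sprintf("type%02d", seq_along(type_counts)), type_counts),
      .before = 1
    )
}

# A reduced synthetic dataset for pipeline tests: one technique/resolution
# block, eight oil types.
small_dataset <- function(seed = 1, noise = list(), n_types = 8) {
  cfg <- synthetic_config(
    n_types = n_types, techniques = "TRANS", resolutions = 8,
    noise = noise, seed = seed
  )
  simulate_oil_dataset(cfg)
}

# Default-conditions dataset and full grid run, computed once and shared
# by the acceptance checks (several criteria are evaluated from one run).
.acceptance_env <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.acceptance_env$dataset)) {
    .acceptance_env$dataset <- simulate_oil_dataset(synthetic_config(seed = 1))
  }
  .acceptance_env$dataset
}

acceptance_records <- function() {
  if (is.null(.acceptance_env$records)) {
    .acceptance_env$records <- run_grid(enumerate_grid(seed = 1),
                                        acceptance_dataset())
  }
  .acceptance_env$records
}
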