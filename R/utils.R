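# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make the retained-variable count depend on parity of the tie).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` with the global RNG seeded to `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs a session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit seed from a base seed and a label, so
# independent random draws (random-feature control, composition jitter,
# replicate noise, ...) never share a stream.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

# Uniform axis spacing, with a relative-tolerance check.
axis_spacing <- function(axis, tol = 1e-6, what = "wavenumber axis") {
  if (length(axis) < 2) {
    return(NA_real_)
  }
  d <- diff(axis)
  h <- mean(d)
  if (h <= 0 || any(abs(d - h) > tol * abs(h))) {
    abort(sprintf("irregular grid: %s is not uniformly spaced", what),
          class = "oilspec_irregular_grid")
  }
  h
}

# Column standard deviations without a per-column loop.
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}
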