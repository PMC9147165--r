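#' Fit a single-response partial least squares model (NIPALS)
#'
#' Classical NIPALS PLS1 on column-mean-centred features and a centred
#' response. Per latent factor: the weight vector is the normalised
#' covariance direction `w = X'y / ||X'y||`, scores `t = Xw`, response
#' loading `c = t'y / t't`, feature loadings `p = X't / t't`, after which
#' `X` and `y` are deflated by the extracted component. The regression
#' vector is composed as `b = W (P'W)^-1 c`, so predictions are
#' `y_hat = (X - x_mean) b + y_mean`.
#'
#' Extraction stops early when the residual covariance norm `||X'y||`
#' drops below `tol` (no predictive variance left); the realised number of
#' factors is recorded in `n_factors` with `truncated = TRUE`.
#'
#' @param X Feature matrix (`n x q`) or a [features] object.
#' @param y Numeric response, length `n`.
#' @param k Number of latent factors, `1 <= k <= min(20, n - 1, q)`.
#' @param tol Early-stop tolerance on `||X'y||`.
#' @return An object of class `pls1` with elements `x_mean`, `y_mean`,
#'   `weights`, `loadings`, `y_loadings`, `coefficients` (the regression
#'   vector `b`), `n_factors`, `truncated`, and the effective `axis` when
#'   the input carried one.
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(12, sd = 0.01)
#' fit <- fit_pls1(X, y, k = 3)
#' predict(fit, X)
#' @export
fit_pls1 <- function(X, y, k, tol = 1e-12) {
  axis <- NULL
  if (inherits(X, "features")) {
    axis <- X$axis
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  q <- ncol(X)
  if (length(y) != n) {
    abort("`y` must have one value per row of `X`")
  }
  if (n < 2) {
    abort("PLS needs at least 2 rows")
  }
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y))) {
    abort("`X` and `y` must be finite")
  }
  k <- stopifnot_scalar_int(k, "k")
  if (k < 1 || k > min(20L, n - 1L, q)) {
    abort(sprintf("`k` must lie in 1..min(20, n - 1, q) = %d", min(20L, n - 1L, q)))
  }
  if (sd(y) == 0) {
    abort("zero-variance response")
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  core <- nipals_pls1(sweep(X, 2, x_mean), y - y_mean, k, tol)

  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = core$W, loadings = core$P, y_loadings = core$cvec,
    coefficients = core$b, n_factors = core$k, truncated = core$truncated,
    axis = axis, n = n, q = q
  ), class = "pls1")
}

# NIPALS PLS1 on already-centred data. Returns weights W, loadings P,
# y-loadings cvec, regression vector b, realised factor count.
nipals_pls1 <- function(Xc, yc, k, tol = 1e-12) {
  q <- ncol(Xc)
  W <- matrix(0, q, k)
  P <- matrix(0, q, k)
  cvec <- numeric(k)
  truncated <- FALSE
  a <- 0L
  for (j in seq_len(k)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      truncated <- TRUE
      break
    }
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    cc <- sum(t_ * yc) / tt
    p <- crossprod(Xc, t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - cc * t_
    W[, j] <- w
    P[, j] <- p
    cvec[j] <- cc
    a <- j
  }
  if (a == 0L) {
    b <- numeric(q)
  } else {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    cvec <- cvec[seq_len(a)]
    b <- as.vector(W %*% solve(crossprod(P, W), cvec))
  }
  list(W = W, P = P, cvec = cvec, b = b, k = a, truncated = truncated)
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1: %d latent factor(s), %d features, n = %d%s>\n",
              x$n_factors, x$q, x$n, if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object A `pls1` fit.
#' @param newdata Feature matrix or [features] object with `q` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  if (inherits(newdata, "features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    abort(sprintf("`newdata` has %d columns; the model expects %d",
                  ncol(newdata), length(object$x_mean)))
  }
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$coefficients +
              object$y_mean)
}

#' @export
tidy.pls1 <- function(x, ...) {
  tibble(
    term = if (is.null(x$axis)) paste0("x", seq_len(x$q)) else sprintf("%g", x$axis),
    wavenumber = if (is.null(x$axis)) NA_real_ else x$axis,
    estimate = x$coefficients
  )
}

#' @export
glance.pls1 <- function(x, ...) {
  tibble(n_factors = x$n_factors, n = x$n, q = x$q, truncated = x$truncated,
         y_mean = x$y_mean)
}

# Orthonormal row-space reduction: returns Z (n x r) with Z Z' = X X' and
# X = Z V' for an orthonormal V. PLS1 predictions computed from row-subsets
# of Z are identical to those from the same subsets of X (all quantities
# involved depend on X only through inner products of its rows), so the
# cross-validation loop can run on an n x r matrix even when q >> n.
reduce_rows <- function(X, tol = 1e-12) {
  K <- tcrossprod(X)
  e <- eigen(K, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * tol
  if (!any(pos)) {
    return(matrix(0, nrow(X), 1))
  }
  e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                          nrow = sum(pos))
}

# One CV fold: fit NIPALS on the kept rows and return held-out predictions
# for every factor count 1..k_max (nested models from a single extraction;
# held-out rows are propagated through the same deflation sequence).
fold_predictions <- function(Xi, yi, Xo, k_max, tol = 1e-12) {
  x_mean <- colMeans(Xi)
  y_mean <- mean(yi)
  Xi <- sweep(Xi, 2, x_mean)
  yi <- yi - y_mean
  Xo <- sweep(Xo, 2, x_mean)
  pred <- matrix(y_mean, nrow(Xo), k_max)
  acc <- rep(y_mean, nrow(Xo))
  for (j in seq_len(k_max)) {
    w <- crossprod(Xi, yi)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      pred[, j:k_max] <- acc
      break
    }
    w <- w / nw
    t_ <- Xi %*% w
    tt <- sum(t_^2)
    cc <- sum(t_ * yi) / tt
    p <- crossprod(Xi, t_) / tt
    Xi <- Xi - tcrossprod(t_, p)
    yi <- yi - cc * t_
    to <- Xo %*% w
    Xo <- Xo - tcrossprod(to, p)
    acc <- acc + cc * as.vector(to)
    pred[, j] <- acc
  }
  pred
}

#' Choose the number of latent factors by leave-one-sample-out
#'
#' Cross-validates PLS1 over factor counts `1..k_max` on the calibration
#' set. When several rows of `X` are replicate spectra of one physical
#' sample, they must be held out together -- leaving single rows out would
#' let a model peek at the held-out sample through its sister replicates
#' and understate the error. Pass the grouping through `groups`; the
#' default treats every row as its own sample.
#'
#' RMSECV(k) is the root-mean-square error over all held-out predictions;
#' `best_k` is the smallest k attaining the minimum.
#'
#' @param X Calibration feature matrix or [features] object.
#' @param y Calibration response.
#' @param k_max Largest factor count to try (default 20; capped at
#'   `min(k_max, n_samples - 2, q)`).
#' @param groups Sample identifier per row (defaults to one row = one
#'   sample).
#' @param tol Early-stop tolerance passed to the NIPALS core.
#' @return An object of class `pls1_cv`: `rmsecv_by_k`, `best_k`, `k_max`.
#' @export
loocv_select <- function(X, y, k_max = 20, groups = NULL, tol = 1e-12) {
  if (inherits(X, "features")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(groups)) groups <- seq_len(n)
  if (length(groups) != n || length(y) != n) {
    abort("`y` and `groups` must have one entry per row of `X`")
  }
  ids <- unique(groups)
  if (length(ids) < 3) {
    abort("leave-one-sample-out needs at least 3 calibration samples")
  }
  k_max <- min(stopifnot_scalar_int(k_max, "k_max"),
               length(ids) - 2L, ncol(X))
  if (k_max < 1) {
    abort("no admissible factor count: too few samples or features")
  }

  # Row-space reduction makes each fold O(n^2) instead of O(n q).
  Z <- if (ncol(X) > nrow(X)) reduce_rows(X) else X

  pred <- matrix(NA_real_, n, k_max)
  for (id in ids) {
    out <- which(groups == id)
    pred[out, ] <- fold_predictions(Z[-out, , drop = FALSE], y[-out],
                                    Z[out, , drop = FALSE], k_max, tol)
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  structure(list(rmsecv_by_k = rmsecv,
                 best_k = which.min(rmsecv),
                 k_max = k_max),
            class = "pls1_cv")
}

#' @export
print.pls1_cv <- function(x, ...) {
  cat(sprintf("<pls1_cv: best k = %d of 1..%d, RMSECV = %.4g>\n",
              x$best_k, x$k_max, x$rmsecv_by_k[x$best_k]))
  invisible(x)
}

#' @export
tidy.pls1_cv <- function(x, ...) {
  tibble(n_factors = seq_len(x$k_max), rmsecv = x$rmsecv_by_k,
         best = seq_len(x$k_max) == x$best_k)
}

#' @export
autoplot.pls1_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$n_factors, y = .data$rmsecv)) +
    geom_line() +
    geom_point(aes(colour = .data$best), show.legend = FALSE) +
    scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    labs(x = "Latent factors", y = "RMSECV") +
    theme_minimal()
}

#' Model quality metrics
#'
#' `r_squared()` is the coefficient of determination
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`; on an independent
#' validation set it can be negative (the model predicts worse than the
#' validation mean). `rmse()` is the root-mean-square error.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return A scalar.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    abort("`y` and `y_hat` must have the same length")
  }
  if (length(y) < 2 || sd(y) == 0) {
    abort("`r_squared` needs at least 2 observations with non-zero variance")
  }
  1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
}

#' @rdname r_squared
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    abort("`y` and `y_hat` must have the same length")
  }
  if (length(y) == 0) {
    abort("`rmse` of an empty vector is undefined")
  }
  sqrt(mean((y - y_hat)^2))
}

#' Serialize a PLS1 model to a flat text file
#'
#' Writes means, regression vector and factor count as `key<TAB>value`
#' lines (vectors comma-separated, full precision), a plain-text snapshot
#' for reproducibility. `read_pls1()` restores an object usable with
#' [predict.pls1()].
#'
#' @param object A `pls1` fit.
#' @param path Output file.
#' @return `path` (write) / a `pls1` object (read).
#' @export
write_pls1 <- function(object, path) {
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(
    paste0("n_factors\t", object$n_factors),
    paste0("y_mean\t", fmt(object$y_mean)),
    paste0("x_mean\t", fmt(object$x_mean)),
    paste0("coefficients\t", fmt(object$coefficients)),
    paste0("axis\t", if (is.null(object$axis)) "" else fmt(object$axis))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pls1
#' @export
read_pls1 <- function(path) {
  kv <- strsplit(readLines(path), "\t", fixed = TRUE)
  vals <- setNames(
    lapply(kv, function(x) if (length(x) > 1) x[[2]] else ""),
    vapply(kv, `[[`, "", 1)
  )
  num <- function(key) as.numeric(strsplit(vals[[key]], ",", fixed = TRUE)[[1]])
  axis <- num("axis")
  structure(list(
    x_mean = num("x_mean"), y_mean = num("y_mean"),
    coefficients = num("coefficients"),
    n_factors = as.integer(vals$n_factors),
    truncated = NA, axis = if (length(axis)) axis else NULL,
    n = NA_integer_, q = length(num("x_mean"))
  ), class = "pls1")
}
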