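#' Enumerate the full model grid
#'
#' The Cartesian product of the six modelling axes: acquisition technique
#' (ATR, TRANS), resolution (2, 4, 8 cm^-1), replicate handling (ALL =
#' three separate spectra per sample, AVG = averaged), variable selection
#' (STD, CORR, CHEM), the 16 preprocessing variants of
#' [preprocess_variants()], and the dependent variables. Over the 13
#' standard responses this yields 2 x 3 x 2 x 3 x 16 x 13 = 7488
#' configurations. The enumeration order is fixed (technique outermost,
#' response innermost) and each row carries a deterministic per-config
#' seed derived from `seed` (used only by the RANDOM control).
#'
#' @param responses Character vector of response names.
#' @param seed Base seed for the per-config seeds.
#' @return A tibble of model configurations with a unique `config_id`.
#' @examples
#' nrow(enumerate_grid())  # 7488
#' @export
enumerate_grid <- function(responses = oil_responses(), seed = 1L) {
  if (length(responses) == 0) {
    abort("`responses` must be non-empty")
  }
  seed <- stopifnot_scalar_int(seed, "seed")
  g <- tidyr::expand_grid(
    technique = c("ATR", "TRANS"),
    resolution = c(2L, 4L, 8L),
    replicate_mode = c("ALL", "AVG"),
    selection = c("STD", "CORR", "CHEM"),
    preprocess = preprocess_variants(),
    response = responses
  )
  g$config_id <- sprintf("%s_R%d_%s_%s_%s_%s", g$technique, g$resolution,
                         g$replicate_mode, g$selection, g$preprocess,
                         g$response)
  g$seed <- vapply(g$config_id, function(id) derive_seed(seed, id),
                   integer(1), USE.NAMES = FALSE)
  g
}

cache_memo <- function(cache, key, expr) {
  if (is.null(cache)) return(force(expr))
  if (is.null(cache[[key]])) cache[[key]] <- force(expr)
  cache[[key]]
}

grid_metric_names <- function() {
  c("n_factors", "rmsecv", "rmsec", "rmsep", "r2_c", "r2_v",
    "cal_range_lo", "cal_range_hi")
}

# Assemble the feature matrix for one configuration, with optional caching
# of the replicate-averaged block and the preprocessed features (shared by
# the selection x response inner cells of the grid).
config_features <- function(config, data, cache = NULL) {
  key <- sprintf("%s_R%d", config$technique, config$resolution)
  block <- data$spectra[[key]]
  if (is.null(block)) {
    abort(sprintf("no spectra block '%s' in the data", key))
  }
  memo <- function(k, expr) cache_memo(cache, k, expr)
  if (config$replicate_mode == "AVG") {
    block <- memo(paste0("avg:", key), average_replicates(block))
  }
  spec <- parse_preprocess(config$preprocess)
  fkey <- sprintf("feat:%s:%s:%s:%d", key, config$replicate_mode,
                  config$preprocess,
                  if (spec$base == "RANDOM") config$seed else 0L)
  feats <- memo(fkey, apply_preprocess(block, spec, seed = config$seed))
  list(features = feats, meta = block$meta)
}

#' Fit and score one grid configuration
#'
#' Runs the full pipeline for a single [enumerate_grid()] row: replicate
#' averaging if requested, preprocessing, variable selection fitted on the
#' calibration rows only, leave-one-sample-out choice of the latent factor
#' count (1..20), a final PLS1 fit, and quality metrics on the calibration
#' and validation rows. In ALL mode every replicate spectrum inherits its
#' sample's split and reference values and contributes one prediction.
#'
#' Degenerate configurations (empty selection, constant response, no
#' usable validation variance) yield a record with `status = "degenerate"`
#' and `NA` metrics rather than an error.
#'
#' @param config One-row tibble (or list) with the [enumerate_grid()]
#'   fields.
#' @param data List with `spectra` (named blocks) and `samples` (split
#'   sample tibble), e.g. from [simulate_oil_dataset()].
#' @param cache Optional environment for cross-config caching (managed by
#'   [run_grid()]).
#' @return A one-row tibble: the config fields, `n_factors`, the five
#'   quality metrics, the calibration range and `status`.
#' @export
run_model <- function(config, data, cache = NULL) {
  config <- as.list(config)
  samples <- validate_samples(data$samples, require_split = TRUE)
  record <- as_tibble(config[c("technique", "resolution", "replicate_mode",
                               "selection", "preprocess", "response",
                               "config_id", "seed")])
  empty <- setNames(as.list(rep(NA_real_, length(grid_metric_names()))),
                    grid_metric_names())

  result <- tryCatch({
    cf <- config_features(config, data, cache)
    idx <- match(cf$meta$sample_id, samples$sample_id)
    if (anyNA(idx)) {
      abort("spectra contain sample_ids missing from the sample table")
    }
    split <- samples$split[idx]
    yrow <- samples[[config$response]][idx]
    cal <- which(split == "calibration")
    val <- which(split == "validation")
    groups <- cf$meta$sample_id[cal]

    sel_key <- sprintf("sel:%s_R%d:%s:%s:%s:%s:%d", config$technique,
                       config$resolution, config$replicate_mode,
                       config$preprocess, config$selection,
                       if (config$selection == "CORR") config$response else "",
                       if (config$preprocess == "RANDOM") config$seed else 0L)
    sel <- cache_memo(cache, sel_key, {
      feats_cal <- features(cf$features$values[cal, , drop = FALSE],
                            cf$features$axis, cf$features$spec)
      switch(config$selection,
        STD = select_by_std(feats_cal),
        CORR = select_by_corr(feats_cal, yrow[cal]),
        CHEM = select_by_chem(cf$features$axis),
        abort(sprintf("unknown selection method: %s", config$selection))
      )
    })
    A <- apply_selection(cf$features, sel)
    X_cal <- A$values[cal, , drop = FALSE]
    X_val <- A$values[val, , drop = FALSE]

    cv <- loocv_select(X_cal, yrow[cal], k_max = 20, groups = groups)
    fit <- fit_pls1(X_cal, yrow[cal], k = cv$best_k)
    pred_cal <- predict(fit, X_cal)
    pred_val <- predict(fit, X_val)

    list(
      n_factors = fit$n_factors,
      rmsecv = cv$rmsecv_by_k[cv$best_k],
      rmsec = rmse(yrow[cal], pred_cal),
      rmsep = rmse(yrow[val], pred_val),
      r2_c = r_squared(yrow[cal], pred_cal),
      r2_v = r_squared(yrow[val], pred_val),
      cal_range_lo = min(yrow[cal]), cal_range_hi = max(yrow[cal])
    )
  }, error = function(e) NULL)

  if (is.null(result) || !all(vapply(result, is.finite, TRUE))) {
    record <- bind_cols(record, as_tibble(empty))
    record$status <- "degenerate"
  } else {
    record <- bind_cols(record, as_tibble(result))
    record$status <- "ok"
  }
  record
}

#' Run many grid configurations
#'
#' Executes [run_model()] for each configuration. Results are independent
#' of execution order. If `out` names a CSV file, records are appended as
#' they complete and -- when the file already holds records from an earlier
#' partial run -- already-completed configurations are skipped, making long
#' runs resumable.
#'
#' @param configs Tibble from [enumerate_grid()] (or a subset).
#' @param data Dataset list (see [run_model()]).
#' @param out Optional CSV path for incremental, resumable output.
#' @param progress Print a progress line every `progress` configs
#'   (`0` = silent).
#' @return Tibble of model records, one row per configuration, in the
#'   order of `configs`.
#' @export
run_grid <- function(configs, data, out = NULL, progress = 0) {
  cache <- new.env(parent = emptyenv())
  done <- NULL
  if (!is.null(out) && file.exists(out)) {
    done <- readr::read_csv(out, show_col_types = FALSE, progress = FALSE)
  }
  records <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    if (!is.null(done) && cfg$config_id %in% done$config_id) {
      records[[i]] <- done[match(cfg$config_id, done$config_id), ]
      next
    }
    rec <- run_model(cfg, data, cache)
    records[[i]] <- rec
    if (!is.null(out)) {
      readr::write_csv(rec, out, append = file.exists(out), progress = FALSE)
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("[%d/%d] %s", i, nrow(configs), cfg$config_id))
    }
  }
  bind_rows(records)
}

#' Share of models reaching each R-squared threshold, per preprocessing
#'
#' For every preprocessing variant and both R-squared types (calibration
#' and validation), the percentage of records at or above each threshold.
#' Thresholds are inclusive. Degenerate records are excluded from the
#' denominators.
#'
#' @param records Record tibble from [run_grid()].
#' @param thresholds Decreasing R-squared cutoffs.
#' @return A long tibble: `preprocess`, `r2_type`, `threshold`, `percent`,
#'   `n_models`.
#' @export
threshold_summary <- function(records,
                              thresholds = c(0.99, 0.95, 0.90, 0.80,
                                             0.70, 0.60, 0.50)) {
  if (nrow(records) == 0) {
    abort("`records` is empty")
  }
  ok <- records[records$status == "ok", ]
  long <- tidyr::pivot_longer(
    ok[, c("preprocess", "r2_c", "r2_v")],
    cols = c("r2_c", "r2_v"), names_to = "r2_type", values_to = "r2"
  )
  out <- tidyr::expand_grid(
    preprocess = preprocess_variants()[preprocess_variants() %in% ok$preprocess],
    r2_type = c("r2_c", "r2_v"),
    threshold = thresholds
  )
  out$percent <- pmap(out, function(preprocess, r2_type, threshold) {
    g <- long$r2[long$preprocess == preprocess & long$r2_type == r2_type]
    if (length(g) == 0) NA_real_ else 100 * mean(g >= threshold)
  }) |> unlist()
  out$n_models <- map_dbl(seq_len(nrow(out)), function(i) {
    sum(long$preprocess == out$preprocess[i] & long$r2_type == out$r2_type[i])
  })
  out
}

#' Share of models good on both sets, by response and design factor
#'
#' For each response and each level of the four design factors (technique,
#' resolution, replicate handling, variable selection), the percentage of
#' records whose calibration AND validation R-squared both reach 0.9, and
#' both reach 0.5. The RANDOM control records are excluded: this table
#' compares acquisition and processing choices on spectral data.
#'
#' @param records Record tibble from [run_grid()].
#' @return A tibble: `response`, `factor`, `level`, `criterion`,
#'   `percent`, `n_models`, `empty_group`.
#' @export
good_model_summary <- function(records) {
  ok <- records[records$status == "ok" & records$preprocess != "RANDOM", ]
  factors <- list(
    technique = c("ATR", "TRANS"),
    resolution = c("2", "4", "8"),
    replicate_mode = c("ALL", "AVG"),
    selection = c("STD", "CORR", "CHEM")
  )
  rows <- list()
  for (resp in unique(records$response)) {
    for (f in names(factors)) {
      for (lev in factors[[f]]) {
        g <- ok[ok$response == resp & as.character(ok[[f]]) == lev, ]
        for (thr in c(0.9, 0.5)) {
          rows[[length(rows) + 1]] <- tibble(
            response = resp, factor = f, level = lev,
            criterion = sprintf("both_r2_ge_%.1f", thr),
            percent = if (nrow(g)) 100 * mean(g$r2_c >= thr & g$r2_v >= thr) else 0,
            n_models = nrow(g),
            empty_group = nrow(g) == 0
          )
        }
      }
    }
  }
  bind_rows(rows)
}

#' Best models per response
#'
#' The `top_n` records per response, ranked by descending validation
#' R-squared, then ascending RMSEP, then ascending factor count.
#'
#' @param records Record tibble from [run_grid()].
#' @param top_n Models to keep per response.
#' @return Tibble of the winning records with full configuration and
#'   metrics.
#' @export
best_models <- function(records, top_n = 3) {
  records |>
    filter(.data$status == "ok") |>
    group_by(.data$response) |>
    arrange(desc(.data$r2_v), .data$rmsep, .data$n_factors,
            .by_group = TRUE) |>
    slice_head(n = top_n) |>
    ungroup()
}

#' Predicted versus reference values for one configuration
#'
#' Refits the configuration and returns one row per spectrum (ALL mode)
#' or per sample (AVG mode) with the reference value, the model
#' prediction and the split -- the data behind a predicted-vs-reference
#' scatter plot.
#'
#' @param config One [enumerate_grid()] row.
#' @param data Dataset list (see [run_model()]).
#' @return A tibble of class `oil_predictions`.
#' @export
model_predictions <- function(config, data) {
  config <- as.list(config)
  samples <- validate_samples(data$samples, require_split = TRUE)
  cf <- config_features(config, data)
  idx <- match(cf$meta$sample_id, samples$sample_id)
  split <- samples$split[idx]
  yrow <- samples[[config$response]][idx]
  cal <- which(split == "calibration")

  feats_cal <- features(cf$features$values[cal, , drop = FALSE],
                        cf$features$axis, cf$features$spec)
  sel <- switch(config$selection,
    STD = select_by_std(feats_cal),
    CORR = select_by_corr(feats_cal, yrow[cal]),
    CHEM = select_by_chem(cf$features$axis)
  )
  A <- apply_selection(cf$features, sel)
  cv <- loocv_select(A$values[cal, , drop = FALSE], yrow[cal], k_max = 20,
                     groups = cf$meta$sample_id[cal])
  fit <- fit_pls1(A$values[cal, , drop = FALSE], yrow[cal], k = cv$best_k)

  out <- tibble(
    sample_id = cf$meta$sample_id,
    replicate = cf$meta$replicate,
    split = split,
    reference = yrow,
    predicted = predict(fit, A$values)
  )
  attr(out, "response") <- config$response
  attr(out, "config_id") <- config$config_id
  class(out) <- c("oil_predictions", class(out))
  out
}

#' @export
autoplot.oil_predictions <- function(object, ...) {
  ggplot(object, aes(x = .data$reference, y = .data$predicted,
                     colour = .data$split)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.8) +
    labs(x = paste("Reference", attr(object, "response")),
         y = "Predicted", colour = NULL,
         title = attr(object, "config_id")) +
    theme_minimal()
}

#' Write the three report tables for a set of records
#'
#' `table1.csv`: threshold summary per preprocessing variant;
#' `table2.csv`: good-model share per response and design factor;
#' `table3.csv`: best models per response.
#'
#' @param records Record tibble from [run_grid()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(threshold_summary(records), file.path(dir, "table1.csv"),
                   progress = FALSE)
  readr::write_csv(good_model_summary(records), file.path(dir, "table2.csv"),
                   progress = FALSE)
  readr::write_csv(best_models(records), file.path(dir, "table3.csv"),
                   progress = FALSE)
  invisible(dir)
}
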