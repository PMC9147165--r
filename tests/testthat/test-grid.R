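test_that("grid enumeration covers the full Cartesian product", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 7488)
  expect_equal(nrow(enumerate_grid("iodine_value")), 576)
  expect_equal(sum(g$preprocess != "RANDOM"), 7020)
  expect_equal(anyDuplicated(g$config_id), 0)
  expect_identical(enumerate_grid(seed = 3), enumerate_grid(seed = 3))
  expect_error(enumerate_grid(character(0)), "non-empty")
})

test_that("a noiseless spectrum-linked response calibrates almost perfectly", {
  ds <- small_dataset(seed = 21, noise = list(additive_sd = 0, baseline_sd = 0,
                                              scatter_sd = 0))
  cfg <- list(technique = "TRANS", resolution = 8L, replicate_mode = "ALL",
              selection = "CHEM", preprocess = "SNV",
              response = "alpha_linolenic", config_id = "t", seed = 1L)
  rec <- run_model(cfg, ds)
  expect_equal(rec$status, "ok")
  expect_gte(rec$r2_c, 0.99)
})

test_that("every selection and preprocessing combination yields a record", {
  ds <- small_dataset(seed = 22)
  for (prep in c("RANDOM", "WA+D1", "WD")) {
    for (sel in c("STD", "CORR", "CHEM")) {
      cfg <- list(technique = "TRANS", resolution = 8L, replicate_mode = "AVG",
                  selection = sel, preprocess = prep,
                  response = "iodine_value",
                  config_id = paste(sel, prep), seed = 5L)
      rec <- run_model(cfg, ds)
      expect_equal(rec$status, "ok", label = paste(sel, prep))
      expect_true(is.finite(rec$r2_v))
    }
  }
})

test_that("replicate rows inherit their sample's split in ALL mode", {
  ds <- small_dataset(seed = 23)
  preds <- model_predictions(
    list(technique = "TRANS", resolution = 8L, replicate_mode = "ALL",
         selection = "CHEM", preprocess = "RAW", response = "linoleic",
         config_id = "t", seed = 1L), ds)
  per_sample <- tapply(preds$split, preds$sample_id,
                       function(s) length(unique(s)))
  expect_true(all(per_sample == 1))
  expect_equal(nrow(preds), nrow(ds$spectra$TRANS_R8$values))
})

test_that("grid execution is deterministic, order-independent and resumable", {
  ds <- small_dataset(seed = 24)
  g <- enumerate_grid(c("iodine_value", "peroxide_value"), seed = 2)
  sub <- g[g$technique == "TRANS" & g$resolution == 8 &
             g$preprocess %in% c("RAW", "SNV", "RANDOM") &
             g$replicate_mode == "AVG", ]
  r1 <- run_grid(sub, ds)
  r2 <- run_grid(sub, ds)
  expect_equal(r1, r2)

  shuffled <- run_grid(sub[sample(nrow(sub)), ], ds)
  expect_equal(dplyr::arrange(shuffled, config_id),
               dplyr::arrange(r1, config_id))

  out <- withr::local_tempfile(fileext = ".csv")
  run_grid(sub[1:4, ], ds, out = out)
  expect_equal(nrow(readr::read_csv(out, show_col_types = FALSE)), 4)
  resumed <- run_grid(sub, ds, out = out)
  expect_equal(resumed$config_id, r1$config_id)
  expect_equal(resumed$r2_v, r1$r2_v, tolerance = 1e-12)
})

test_that("threshold summaries count inclusively and nest monotonically", {
  rec <- tibble::tibble(
    preprocess = rep(c("RAW", "SNV"), each = 3),
    status = "ok",
    r2_c = c(1, 1, 1, 0.96, 0.5, 0.2),
    r2_v = c(1, 1, 1, 0.91, 0.5, -0.4)
  )
  ts <- threshold_summary(rec)
  raw <- ts[ts$preprocess == "RAW", ]
  expect_true(all(raw$percent == 100))
  # boundary: r2 = 0.5 counts at the 0.5 threshold
  snv_v <- ts[ts$preprocess == "SNV" & ts$r2_type == "r2_v", ]
  expect_equal(snv_v$percent[snv_v$threshold == 0.5], 100 * 2 / 3)
  # monotone in the threshold
  for (pp in c("RAW", "SNV")) {
    for (ty in c("r2_c", "r2_v")) {
      p <- ts$percent[ts$preprocess == pp & ts$r2_type == ty]
      expect_true(all(diff(p) >= 0))  # thresholds are listed decreasing
    }
  }
  expect_error(threshold_summary(rec[0, ]), "empty")
})

test_that("good-model shares require both coefficients above the cutoff", {
  rec <- tibble::tibble(
    technique = "TRANS", resolution = 8L, replicate_mode = "ALL",
    selection = "STD", preprocess = c("RAW", "RAW", "RANDOM"),
    response = "linoleic", status = "ok",
    r2_c = c(0.95, 0.92, 1.0), r2_v = c(0.4, 0.91, 1.0)
  )
  gm <- good_model_summary(rec)
  trans <- gm[gm$factor == "technique" & gm$level == "TRANS", ]
  # RANDOM is excluded; of the two spectral records only one passes both
  expect_equal(trans$percent[trans$criterion == "both_r2_ge_0.9"], 50)
  expect_equal(trans$percent[trans$criterion == "both_r2_ge_0.5"], 50)
  atr <- gm[gm$factor == "technique" & gm$level == "ATR", ]
  expect_true(all(atr$empty_group))
  expect_true(all(atr$percent == 0))
})

test_that("best models rank by validation quality then parsimony", {
  rec <- tibble::tibble(
    technique = "TRANS", resolution = 8L, replicate_mode = "ALL",
    selection = "STD", preprocess = "RAW", response = "linoleic",
    config_id = paste0("m", 1:5), seed = 1L, status = "ok",
    n_factors = c(3, 2, 5, 1, 4),
    rmsecv = 1, rmsec = 1,
    rmsep = c(1.0, 2.0, 0.5, 0.2, 0.6),
    r2_c = 0.9, r2_v = c(0.9, 0.8, 0.95, 0.7, 0.95),
    cal_range_lo = 0, cal_range_hi = 1
  )
  bm <- best_models(rec, top_n = 3)
  # r2_v tie between m3 and m5 broken by the smaller RMSEP, then 0.9
  expect_equal(bm$config_id, c("m3", "m5", "m1"))
  expect_equal(nrow(best_models(rec[1:2, ], top_n = 3)), 2)
})
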