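test_that("spectra CSV round trip is exact and shapes propagate", {
  set.seed(42)
  sp <- toy_spectra(matrix(rnorm(30), 3, 10),
                    sample_id = c("a", "a", "b"), replicate = c(1L, 2L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_identical(back$values, sp$values)
  expect_identical(back$axis, sp$axis)
  expect_equal(back$meta, sp$meta)

  # shape propagation: axis + 2 spectra, 5 wavenumbers
  sp2 <- toy_spectra(matrix(1:10 / 10, 2, 5))
  expect_equal(dim(sp2), c(2L, 5L))
})

test_that("empty spectra files round trip with n = 0", {
  sp <- spectra(seq(600, 636, by = 4), matrix(numeric(0), 0, 10),
                tibble::tibble(sample_id = character(), technique = character(),
                               resolution = integer(), replicate = integer()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  expect_equal(nrow(read_spectra_csv(path)$values), 0)
})

test_that("a descending axis is normalised to ascending with rows reversed", {
  ax <- seq(4000, 600, by = -4)
  v <- matrix(seq_along(ax), 1)
  sp <- toy_spectra(v, axis = ax)
  expect_true(!is.unsorted(sp$axis))
  expect_equal(sp$values[1, 1], v[1, length(ax)])  # value follows its wavenumber
})

test_that("invalid spectra are rejected", {
  expect_error(toy_spectra(matrix(1:3, 1), axis = c(600, 604, 612)),
               "irregular grid")
  expect_error(toy_spectra(matrix(c(1, NaN), 1), axis = c(600, 604)),
               "finite")
  expect_error(
    spectra(c(600, 604), matrix(1:4 / 4, 2),
            tibble::tibble(sample_id = c("a", "b"),
                           technique = c("ATR", "TRANS"),
                           resolution = 8, replicate = 1L)),
    "inconsistent metadata")
  # technique-specific axis coverage
  expect_error(toy_spectra(matrix(1:2 / 2, 1), axis = c(500, 504)),
               "TRANS axis")
  expect_silent(toy_spectra(matrix(1:2 / 2, 1), axis = c(500, 504),
                            technique = "ATR"))
  # non-numeric cell in a CSV names the location
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,a|TRANS|R8|rep1", "600,0.1", "604,oops"), path)
  expect_error(read_spectra_csv(path), "non-numeric")
})

test_that("replicate averaging is the unweighted mean, one row per sample", {
  sp <- toy_spectra(rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2)),
                    sample_id = rep("s1", 3), replicate = 1:3)
  avg <- average_replicates(sp)
  expect_equal(avg$values, matrix(c(2, 2, 2), 1))
  expect_equal(avg$meta$replicate, 1L)

  # single replicate is returned unchanged
  one <- toy_spectra(matrix(1:5 / 5, 1))
  expect_equal(average_replicates(one)$values, one$values)

  # 37 samples x 3 replicates -> 37 rows, order of first appearance
  ids <- sprintf("S%02d", 1:37)
  sp37 <- toy_spectra(matrix(rnorm(37 * 3 * 4), 111, 4),
                      sample_id = rep(ids, each = 3),
                      replicate = rep(1:3, 37))
  expect_equal(average_replicates(sp37)$meta$sample_id, ids)
})

test_that("axis spacing validates against nominal resolution", {
  mk <- function(h, res) toy_spectra(matrix(1:3 / 3, 1),
                                     axis = seq(600, by = h, length.out = 3),
                                     resolution = res)
  expect_true(validate_resolution(mk(4, 8)))   # half-spacing convention
  expect_true(validate_resolution(mk(8, 8)))   # full-spacing convention
  expect_false(validate_resolution(mk(32, 2)))
})

test_that("calibration/validation split follows the per-type rules", {
  counts <- c(3, 2, 4, 2, 3, 3, 1, 2, 2, 4, 2, 2, 1, 1, 1, 1, 3)
  tbl <- toy_samples(counts)
  out <- assign_split(tbl, seed = 7)
  expect_equal(sum(out$split == "calibration"), 29)
  expect_equal(sum(out$split == "validation"), 8)
  # conservation and per-type calibration count
  expect_setequal(out$sample_id, tbl$sample_id)
  ncal <- tapply(out$split == "calibration", out$oil_type, sum)
  expect_true(all(ncal %in% 1:2))
  # determinism
  expect_identical(assign_split(tbl, seed = 7), out)

  # all singleton types -> everything calibration
  ones <- toy_samples(rep(1, 5))
  expect_true(all(assign_split(ones, seed = 1)$split == "calibration"))
})

test_that("holders of a global extreme are kept out of validation", {
  # type01 has 3 samples; sample A holds the global max iodine value while
  # B and C are interior on every response (extremes live in other types).
  tbl <- toy_samples(c(3, 3, 3), seed = 5)
  y <- oil_responses()
  tbl[, y] <- lapply(tbl[, y], function(v) pmin(pmax(v, 20), 80))
  tbl[4, y] <- as.list(rep(1, 13))    # global minima (type02)
  tbl[7, y] <- as.list(rep(99, 13))   # global maxima (type03)
  tbl$iodine_value[1] <- 999          # sample A: global max iodine
  chosen_A <- vapply(1:100, function(s) {
    out <- assign_split(tbl, seed = s)
    out$split[1] == "validation"
  }, logical(1))
  expect_false(any(chosen_A))
  # but the type still sends exactly one of B, C to validation
  out <- assign_split(tbl, seed = 3)
  expect_equal(sum(out$split[1:3] == "validation"), 1)
})
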