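#' Spectral components of the synthetic oil model
#'
#' The generator describes each oil as a mixture of eight chemical
#' components: six fatty-acyl species (palmitic, stearic, oleic, elaidic,
#' linoleic, alpha-linolenic), an unsaponifiable fraction (sterols,
#' tocopherols) and a hydroperoxide oxidation marker. `oil_components()`
#' returns their names in canonical order; `iodine_coefficients()` the
#' iodine-value contribution of each component per percent (saturated
#' acyls 0, one double bond 0.90, two 1.81, three 2.74 -- chosen so a pure
#' unsaturated acid's iodine value lands at textbook magnitudes).
#'
#' @return Character vector / named numeric vector of length 8.
#' @export
oil_components <- function() {
  c("palmitic", "stearic", "oleic", "elaidic", "linoleic", "alpha_linolenic",
    "unsaponifiable", "hydroperoxide")
}

#' @rdname oil_components
#' @export
iodine_coefficients <- function() {
  setNames(c(0, 0, 0.90, 0.90, 1.81, 2.74, 0, 0), oil_components())
}

#' Default Gaussian band library
#'
#' Absorption bands per component as Gaussian profiles (centre and width
#' in cm^-1, amplitude in absorbance units). Every acyl component shares
#' the ester carbonyl (~1745), C-O (~1160) and C-H stretch (2850--2930)
#' bands; unsaturated components add the olefinic =C-H stretch just above
#' 3000 cm^-1 with amplitude growing with double-bond count, the trans
#' isomer its distinctive ~966 cm^-1 bending band, and the non-acyl
#' components broad O-H features. The library is ordinary data -- tests and
#' users can supply tiny toy libraries through the same interface
#' ([read_band_library()]).
#'
#' @return A tibble with columns `component`, `center`, `width`,
#'   `amplitude`.
#' @export
default_band_library <- function() {
  tribble_rows <- list(
    # component,          center, width, amplitude
    c("palmitic",          720,  10, 0.18), c("palmitic",         1112,  10, 0.12),
    c("palmitic",         1465,  12, 0.32), c("palmitic",         1745,  14, 0.80),
    c("palmitic",         1160,  16, 0.50), c("palmitic",         2855,  14, 0.60),
    c("palmitic",         2925,  16, 0.85),
    c("stearic",           730,  10, 0.20), c("stearic",          1300,  10, 0.10),
    c("stearic",          1465,  12, 0.34), c("stearic",          1745,  14, 0.78),
    c("stearic",          1160,  16, 0.48), c("stearic",          2855,  14, 0.66),
    c("stearic",          2925,  16, 0.92),
    c("oleic",            1465,  12, 0.28), c("oleic",            1655,  12, 0.05),
    c("oleic",            1745,  14, 0.76), c("oleic",            1160,  16, 0.46),
    c("oleic",            2855,  14, 0.55), c("oleic",            2925,  16, 0.80),
    c("oleic",            3005,  12, 0.12),
    c("elaidic",           966,  10, 0.35), c("elaidic",          1670,  12, 0.04),
    c("elaidic",          1745,  14, 0.76), c("elaidic",          1160,  16, 0.46),
    c("elaidic",          2855,  14, 0.55), c("elaidic",          2920,  16, 0.80),
    c("elaidic",          3000,  12, 0.12),
    c("linoleic",         1099,  10, 0.15), c("linoleic",         1652,  12, 0.09),
    c("linoleic",         1745,  14, 0.75), c("linoleic",         1160,  16, 0.45),
    c("linoleic",         2855,  14, 0.52), c("linoleic",         2925,  16, 0.78),
    c("linoleic",         3008,  12, 0.24),
    c("alpha_linolenic",   914,  10, 0.18), c("alpha_linolenic",  1650,  12, 0.12),
    c("alpha_linolenic",  1745,  14, 0.74), c("alpha_linolenic",  1160,  16, 0.44),
    c("alpha_linolenic",  2855,  14, 0.50), c("alpha_linolenic",  2925,  16, 0.76),
    c("alpha_linolenic",  3012,  12, 0.36),
    c("unsaponifiable",   1050,  18, 0.25), c("unsaponifiable",   1600,  16, 0.15),
    c("unsaponifiable",   2935,  18, 0.20), c("unsaponifiable",   3450,  45, 0.30),
    c("hydroperoxide",     830,  12, 0.10), c("hydroperoxide",    3430,  45, 0.25)
  )
  m <- do.call(rbind, lapply(tribble_rows, function(r) {
    tibble(component = r[1], center = as.numeric(r[2]),
           width = as.numeric(r[3]), amplitude = as.numeric(r[4]))
  }))
  validate_band_library(m)
}

validate_band_library <- function(bands) {
  bands <- as_tibble(bands)
  need <- c("component", "center", "width", "amplitude")
  if (!all(need %in% names(bands))) {
    abort("band library needs columns component, center, width, amplitude")
  }
  if (any(bands$width <= 0) || any(bands$amplitude < 0)) {
    abort("band widths must be positive and amplitudes non-negative")
  }
  bands
}

#' @rdname default_band_library
#' @param path CSV path with columns `component`, `center`, `width`,
#'   `amplitude`.
#' @export
read_band_library <- function(path) {
  validate_band_library(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE))
}

#' Evaluate a component's spectrum from its bands
#'
#' Sum of Gaussian profiles `amplitude * exp(-(v - center)^2 / (2 width^2))`
#' over the rows of `bands`, evaluated at the wavenumbers in `axis`.
#'
#' @param bands Data frame with `center`, `width`, `amplitude` (one
#'   component's rows of a band library).
#' @param axis Wavenumber vector.
#' @return Numeric vector, one absorbance per axis point.
#' @export
component_spectrum <- function(bands, axis) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-(axis - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  out
}

# Target ranges for the synthetic dependent variables (the calibration
# ranges the generator aims its marginal distributions at).
quality_ranges <- function() {
  list(
    palmitic = c(1.74, 9.90), linoleic = c(6.63, 80.00),
    alpha_linolenic = c(0.00, 68.50), oleic = c(7.28, 34.50),
    elaidic = c(0.00, 4.25), stearic = c(0.00, 5.98),
    unsaponifiable_matter = c(0.33, 2.20), acid_value = c(0.112, 11.2),
    saponification_value = c(178, 196), ester_value = c(176, 194),
    hydroxyl_value = c(2.70, 19.4), iodine_value = c(99, 204),
    peroxide_value = c(9.29, 123)
  )
}

#' Synthetic dataset configuration
#'
#' Defines the study design the generator emulates: ~17 oil types with one
#' to four samples each (37 samples under the default design), three
#' replicate spectra per sample, both acquisition techniques (ATR
#' 500--4000 cm^-1, transmission 600--4000 cm^-1) at resolutions 2, 4 and
#' 8 cm^-1 with point spacing of half the resolution, and thirteen
#' dependent variables whose linkage to the spectra is tunable per
#' response (1 = fully spectrum-determined, 0 = pure noise).
#'
#' @param n_types Number of oil types. With the default 17, per-type
#'   sample counts follow the canonical 37-sample design; otherwise counts
#'   are drawn uniformly from `samples_per_type`.
#' @param samples_per_type Range of per-type sample counts for
#'   non-default `n_types`.
#' @param replicates Replicate spectra per sample (1..3).
#' @param techniques,resolutions Acquisition axes to simulate.
#' @param noise List: `additive_sd` (a.u., per-point noise at 8 cm^-1,
#'   scaled up as `sqrt(8/resolution)` at finer resolutions),
#'   `baseline_order` and `baseline_sd` (random polynomial baseline),
#'   `scatter_sd` (log-sd of the per-replicate multiplicative scatter
#'   factor).
#' @param linkage Named vector over [oil_responses()] in `[0, 1]`.
#' @param bands Band library (see [default_band_library()]).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `synthetic_config` object (a validated list).
#' @export
synthetic_config <- function(n_types = 17,
                             samples_per_type = c(1, 4),
                             replicates = 3,
                             techniques = c("ATR", "TRANS"),
                             resolutions = c(2, 4, 8),
                             noise = list(additive_sd = 0.003,
                                          baseline_order = 2,
                                          baseline_sd = 0.004,
                                          scatter_sd = 0.08),
                             linkage = NULL,
                             bands = default_band_library(),
                             seed = 1L) {
  default_linkage <- setNames(rep(0.1, 13), oil_responses())
  default_linkage[fatty_acid_responses()] <- 1
  default_linkage["iodine_value"] <- 1
  default_linkage["unsaponifiable_matter"] <- 0.8
  if (!is.null(linkage)) {
    default_linkage[names(linkage)] <- linkage
  }
  if (any(default_linkage < 0 | default_linkage > 1)) {
    abort("`linkage` values must lie in [0, 1]")
  }
  noise <- modifyList(list(additive_sd = 0.003, baseline_order = 2,
                           baseline_sd = 0.004, scatter_sd = 0.08), noise)
  if (!all(techniques %in% c("ATR", "TRANS")) ||
      !all(resolutions %in% c(2, 4, 8))) {
    abort("techniques must be ATR/TRANS and resolutions 2/4/8")
  }
  if (!replicates %in% 1:3) {
    abort("`replicates` must be 1, 2 or 3")
  }
  structure(list(
    n_types = stopifnot_scalar_int(n_types, "n_types"),
    samples_per_type = samples_per_type,
    replicates = as.integer(replicates),
    techniques = techniques, resolutions = resolutions,
    noise = noise, linkage = default_linkage,
    bands = validate_band_library(bands),
    seed = stopifnot_scalar_int(seed, "seed")
  ), class = "synthetic_config")
}

# Per-type sample counts of the canonical 37-sample / 17-type design.
canonical_type_counts <- function() {
  c(3L, 2L, 4L, 2L, 3L, 3L, 1L, 2L, 2L, 4L, 2L, 2L, 1L, 1L, 1L, 1L, 3L)
}

#' Derive the thirteen dependent variables from a composition
#'
#' Fatty-acid responses are the composition entries themselves; the iodine
#' value is the composition-weighted sum of [iodine_coefficients()]. Each
#' remaining response blends a defined linear function of the composition
#' (the "signal", rescaled into its plausible pharmacopoeial range) with
#' independent uniform noise in the same range, weighted by that
#' response's linkage: `value = linkage * signal + (1 - linkage) * noise`.
#'
#' @param composition Named vector over [oil_components()], summing to 100.
#' @param linkage Named linkage vector over [oil_responses()].
#' @param noise_seed Seed for the independent noise draws.
#' @return Named numeric vector over [oil_responses()].
#' @examples
#' comp <- setNames(c(0, 0, 0, 0, 0, 100, 0, 0), oil_components())
#' derive_quality_values(comp, synthetic_config()$linkage, 1)[["iodine_value"]]
#' @export
derive_quality_values <- function(composition, linkage, noise_seed) {
  if (abs(sum(composition) - 100) > 1e-6) {
    abort("`composition` must sum to 100")
  }
  rng <- quality_ranges()
  scale_into <- function(s, s_range, target) {
    u <- (s - s_range[1]) / (s_range[2] - s_range[1])
    target[1] + (target[2] - target[1]) * pmin(pmax(u, 0), 1)
  }
  signals <- c(
    unsaponifiable_matter = unname(composition["unsaponifiable"]),
    acid_value = scale_into(composition[["hydroperoxide"]], c(0.1, 1.5),
                            rng$acid_value),
    saponification_value = scale_into(
      composition[["palmitic"]] + composition[["stearic"]], c(2, 35),
      rng$saponification_value),
    ester_value = scale_into(100 - composition[["unsaponifiable"]] -
                               composition[["hydroperoxide"]], c(96.3, 99.6),
                             rng$ester_value),
    hydroxyl_value = scale_into(composition[["unsaponifiable"]], c(0.33, 2.2),
                                rng$hydroxyl_value),
    peroxide_value = scale_into(composition[["hydroperoxide"]], c(0.1, 1.5),
                                rng$peroxide_value)
  )
  out <- setNames(numeric(13), oil_responses())
  out[fatty_acid_responses()] <- composition[fatty_acid_responses()]
  out["iodine_value"] <- sum(composition * iodine_coefficients()[names(composition)])
  with_seed(noise_seed, {
    for (resp in names(signals)) {
      lam <- linkage[[resp]]
      u <- runif(1, rng[[resp]][1], rng[[resp]][2])
      out[resp] <- lam * signals[[resp]] + (1 - lam) * u
    }
  })
  pmax(out, 0)
}

# Dirichlet-style draw: independent gammas, renormalised.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a full synthetic oil dataset
#'
#' Draws a mean composition per oil type (a broad Dirichlet over the six
#' fatty acyls, plus uniform unsaponifiable and hydroperoxide fractions),
#' jitters it per sample, derives the thirteen reference values
#' ([derive_quality_values()]), and renders replicate spectra for every
#' requested technique/resolution block by Beer-Lambert mixing of the
#' component band spectra. Each replicate receives a multiplicative
#' scatter factor `exp(N(0, scatter_sd))`, a random polynomial baseline,
#' and additive noise whose standard deviation grows as
#' `sqrt(8/resolution)` (finer resolution, more points, more noise). ATR
#' spectra are additionally shaped by a `1000/wavenumber` penetration-depth
#' envelope and extend down to 500 cm^-1.
#'
#' The calibration/validation split is assigned with [assign_split()]
#' using a seed derived from `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `spectra` (named list of [spectra] blocks,
#'   keys like `"TRANS_R8"`), `samples` (sample tibble with `split`),
#'   `ground_truth` (list of `compositions` and `replicate_effects`
#'   tibbles) and `config`.
#' @examples
#' ds <- simulate_oil_dataset(synthetic_config(seed = 7))
#' names(ds$spectra)
#' dplyr::count(ds$samples, split)
#' @export
simulate_oil_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  comps <- oil_components()
  alpha <- c(palmitic = 1.6, stearic = 0.9, oleic = 2.5, elaidic = 0.25,
             linoleic = 3.0, alpha_linolenic = 0.7)

  counts <- if (cfg$n_types == 17) {
    canonical_type_counts()
  } else {
    with_seed(derive_seed(cfg$seed, "type_counts"),
              sample(seq(cfg$samples_per_type[1], cfg$samples_per_type[2]),
                     cfg$n_types, replace = TRUE))
  }
  types <- sprintf("type%02d", seq_len(cfg$n_types))

  type_means <- with_seed(derive_seed(cfg$seed, "type_means"), {
    lapply(seq_len(cfg$n_types), function(i) {
      fatty <- rdirichlet1(alpha)
      unsap <- runif(1, 0.33, 2.2)
      marker <- runif(1, 0.1, 1.5)
      setNames(c(fatty * (100 - unsap - marker), unsap, marker), comps)
    })
  })

  kappa <- 2000  # within-type Dirichlet concentration (few-percent jitter)
  compositions <- with_seed(derive_seed(cfg$seed, "compositions"), {
    rows <- list()
    s <- 0
    for (i in seq_len(cfg$n_types)) {
      for (j in seq_len(counts[i])) {
        s <- s + 1
        frac <- rdirichlet1(type_means[[i]] / 100 * kappa)
        rows[[s]] <- tibble(
          sample_id = sprintf("S%02d", s), oil_type = types[i],
          component = comps, percent = 100 * frac
        )
      }
    }
    bind_rows(rows)
  })
  sample_ids <- unique(compositions$sample_id)
  n_samples <- length(sample_ids)
  comp_mat <- matrix(compositions$percent, nrow = n_samples, byrow = TRUE,
                     dimnames = list(sample_ids, comps))

  y <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    derive_quality_values(comp_mat[i, ], cfg$linkage,
                          derive_seed(cfg$seed, paste0("quality:", sample_ids[i])))
  }))
  samples <- bind_cols(
    tibble(sample_id = sample_ids,
           oil_type = compositions$oil_type[match(sample_ids, compositions$sample_id)]),
    as_tibble(y)
  )
  samples <- assign_split(samples, derive_seed(cfg$seed, "split"))

  band_split <- split(cfg$bands, cfg$bands$component)
  blocks <- list()
  effects <- list()
  for (tech in cfg$techniques) {
    lo <- if (tech == "ATR") 500 else 600
    for (res in cfg$resolutions) {
      axis <- seq(lo, 4000, by = res / 2)
      C <- do.call(rbind, lapply(comps, function(cm) {
        component_spectrum(band_split[[cm]], axis)
      }))
      if (tech == "ATR") {
        C <- sweep(C, 2, 1000 / axis, `*`)  # penetration-depth proxy
      }
      clean <- comp_mat %*% C / 100
      key <- sprintf("%s_R%d", tech, res)
      nrep <- cfg$replicates
      noise_scale <- cfg$noise$additive_sd * sqrt(8 / res)
      u <- 2 * (axis - axis[1]) / (axis[length(axis)] - axis[1]) - 1
      vals <- matrix(0, n_samples * nrep, length(axis))
      meta <- list()
      eff <- list()
      with_seed(derive_seed(cfg$seed, paste0("noise:", key)), {
        r <- 0
        for (i in seq_len(n_samples)) {
          for (k in seq_len(nrep)) {
            r <- r + 1
            scatter <- exp(rnorm(1, 0, cfg$noise$scatter_sd))
            bcoef <- rnorm(cfg$noise$baseline_order + 1, 0, cfg$noise$baseline_sd)
            baseline <- as.vector(outer(u, 0:cfg$noise$baseline_order, `^`) %*% bcoef)
            vals[r, ] <- clean[i, ] * scatter + baseline +
              rnorm(length(axis), 0, noise_scale)
            meta[[r]] <- tibble(sample_id = sample_ids[i], technique = tech,
                                resolution = res, replicate = k)
            eff[[r]] <- tibble(sample_id = sample_ids[i], technique = tech,
                               resolution = res, replicate = k,
                               scatter = scatter,
                               baseline = list(bcoef))
          }
        }
      })
      blocks[[key]] <- spectra(axis, vals, bind_rows(meta))
      effects[[key]] <- bind_rows(eff)
    }
  }

  list(
    spectra = blocks,
    samples = samples,
    ground_truth = list(
      type_means = tibble(oil_type = rep(types, each = length(comps)),
                          component = rep(comps, cfg$n_types),
                          percent = unlist(type_means, use.names = FALSE)),
      compositions = compositions,
      replicate_effects = bind_rows(effects)
    ),
    config = cfg
  )
}

#' Write a simulated dataset to plain-text files
#'
#' One spectra CSV per technique/resolution block
#' (`spectra_<TECH>_R<res>.csv`), a `samples.csv` with the reference
#' values and split, and a `ground_truth.csv` with the latent per-sample
#' compositions.
#'
#' @param dataset Result of [simulate_oil_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_oil_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(dataset$spectra)) {
    write_spectra_csv(dataset$spectra[[key]],
                      file.path(dir, sprintf("spectra_%s.csv", key)))
  }
  write_samples_csv(dataset$samples, file.path(dir, "samples.csv"))
  readr::write_csv(dataset$ground_truth$compositions,
                   file.path(dir, "ground_truth.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_oil_dataset()]
#'
#' @param dir Directory containing `spectra_*.csv` and `samples.csv`.
#' @return A list with `spectra` and `samples`, usable with [run_model()].
#' @export
read_oil_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^spectra_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no spectra_*.csv files found in %s", dir))
  }
  blocks <- lapply(files, read_spectra_csv)
  names(blocks) <- sub("^spectra_(.*)\\.csv$", "\\1", basename(files))
  list(spectra = blocks,
       samples = read_samples_csv(file.path(dir, "samples.csv")))
}
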