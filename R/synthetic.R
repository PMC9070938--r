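# Synthetic inputs with known ground truth.
#
# The generator emulates the statistical structure of the real inputs: monthly
# ocean indices as cross-correlated AR(1) series with seasonal persistence; a
# negative linear link from the winter value of one driver index to regional
# summer kelp extent, with Gaussian noise and truncation at zero; kelp extent
# allocated over 0.1-degree latitude bands and 30x30 m pixels; cloud dropout
# that removes a fraction of a band-year's pixels; and an optional post-split
# suppression regime in which observed canopy is scaled down independently of
# the environment (the herbivory-decoupling scenario).

#' Standard deviation of a 3-month seasonal mean of a unit-variance AR(1)
#' @param phi Monthly lag-1 autocorrelation, `|phi| < 1`.
#' @return `sqrt((3 + 4*phi + 2*phi^2) / 9)`.
#' @export
seasonal_mean_sd <- function(phi) {
  stopifnot(abs(phi) < 1)
  sqrt((3 + 4 * phi + 2 * phi^2) / 9)
}

#' AR(1) coefficient giving a target correlation between adjacent seasons
#'
#' For a unit-variance monthly AR(1), the correlation between the means of two
#' adjacent 3-month blocks (e.g. winter JFM and spring AMJ) is
#' `(phi + 2*phi^2 + 3*phi^3 + 2*phi^4 + phi^5) / (3 + 4*phi + 2*phi^2)`.
#' This inverts that map.
#'
#' @param rho Target season-to-season correlation in `[0, 0.95]`.
#' @return The monthly AR(1) coefficient.
#' @export
ar1_coef_for_season_cor <- function(rho) {
  stopifnot(rho >= 0, rho <= 0.95)
  if (rho == 0) return(0)
  f <- function(phi) {
    (phi + 2 * phi^2 + 3 * phi^3 + 2 * phi^4 + phi^5) /
      (3 + 4 * phi + 2 * phi^2) - rho
  }
  stats::uniroot(f, c(0, 0.9999), tol = 1e-10)$root
}

#' Noise standard deviation giving a target R-squared for the kelp link
#'
#' With kelp `E = alpha + beta * w + eps` and `w` the winter mean of a
#' unit-variance AR(1), the expected R-squared is
#' `beta^2 var(w) / (beta^2 var(w) + sd^2)`; this solves for `sd`.
#'
#' @param beta Link slope (km2 per index unit).
#' @param phi Monthly AR(1) coefficient of the index.
#' @param r2 Target R-squared in (0, 1).
#' @return Noise standard deviation in km2.
#' @export
noise_sd_for_r2 <- function(beta, phi, r2) {
  stopifnot(r2 > 0, r2 < 1)
  abs(beta) * seasonal_mean_sd(phi) * sqrt((1 - r2) / r2)
}

#' Build a synthetic scenario configuration
#'
#' Defaults state the world of the study system: the 1991-2020 shared data
#' period with the 2014 regime split; the 38-40 N domain split at Point Arena
#' (39 N) into 10 bands of 0.1 degrees per region; per-region linear links
#' calibrated to the selected winter models (north: 3.04 - 0.77 x, expected
#' R-squared 0.87; south: 5.52 - 0.19 x, expected R-squared 0.57), with noise
#' derived from those targets; strong winter-spring index persistence
#' (season-to-season correlation 0.8) and moderate cross-index correlation;
#' and a cloud model tuned once so that roughly 20% of region-years fail QC,
#' as in the observed record (5-7 missing years out of 30).
#'
#' @param years Kelp years covered. Default 1991:2020.
#' @param split_year First post-regime year. Default 2014.
#' @param origin,width,upper,split_latitude Band geometry (degrees N).
#' @param pixels_per_band Pixels simulated per band. Default 1200 (enough
#'   capacity for the largest annual extents at 900 m2 per pixel).
#' @param regions Named list; each entry a list with `alpha` (km2), `beta`
#'   (km2 per index unit) and `target_r2`.
#' @param noise_sd Optional named numeric vector overriding the derived
#'   per-region noise standard deviation (km2).
#' @param driver_index Name of the index whose winter mean drives kelp.
#' @param index_names All indices to generate.
#' @param season_cor Target correlation between adjacent seasonal means of
#'   one index (sets the monthly AR(1) coefficient). Default 0.8.
#' @param phi Monthly AR(1) coefficient; overrides `season_cor` when given.
#' @param cross_cor Common cross-correlation of the latent indices. Default
#'   0.6.
#' @param cross_cor_matrix Optional full correlation matrix (dimension =
#'   number of indices) overriding `cross_cor`.
#' @param sst_offset,sst_scale SST-like series are `offset + scale * latent`
#'   (latent is a warm-positive thermal anomaly). Defaults 11.6 C and 0.8 C,
#'   winter conditions off Point Arena.
#' @param beuti_scale BEUTI-like series are `-scale * latent` (upwelling
#'   opposes warm anomalies). Default 5 index units.
#' @param cloud_prob Probability that a band-year suffers cloud dropout.
#'   Default 0.08.
#' @param cloud_fraction Fraction of the band's pixels removed when dropout
#'   strikes. Default 0.3 (enough to trip the 90% pixel-count QC rule).
#' @param suppression_factor Multiplier on observed canopy for years at or
#'   after `split_year`; 1 disables the regime shift.
#' @return An object of class `scenario_config` (a validated list with the
#'   resolved `phi` and per-region `noise_sd` filled in).
#' @export
scenario_config <- function(years = 1991:2020, split_year = 2014,
                            origin = 38, width = 0.1, upper = 40,
                            split_latitude = 39, pixels_per_band = 1200,
                            regions = list(
                              north = list(alpha = 3.04, beta = -0.77,
                                           target_r2 = 0.87),
                              south = list(alpha = 5.52, beta = -0.19,
                                           target_r2 = 0.57)
                            ),
                            noise_sd = NULL,
                            driver_index = "MOCI_south",
                            index_names = c("MOCI_south", "MOCI_central",
                                            "MOCI_north", "SST_N14", "SST_N13",
                                            "BEUTI_37N", "BEUTI_39N",
                                            "BEUTI_41N"),
                            season_cor = 0.8, phi = NULL,
                            cross_cor = 0.6, cross_cor_matrix = NULL,
                            sst_offset = 11.6, sst_scale = 0.8,
                            beuti_scale = 5,
                            cloud_prob = 0.08, cloud_fraction = 0.3,
                            suppression_factor = 1) {
  if (is.null(phi)) phi <- ar1_coef_for_season_cor(season_cor)
  stopifnot(abs(phi) < 1, pixels_per_band >= 1,
            cloud_prob >= 0, cloud_prob <= 1,
            cloud_fraction >= 0, cloud_fraction <= 1,
            suppression_factor > 0, suppression_factor <= 1,
            driver_index %in% index_names,
            upper > split_latitude, split_latitude > origin)
  k <- length(index_names)
  if (is.null(cross_cor_matrix)) {
    cross_cor_matrix <- matrix(cross_cor, k, k)
    diag(cross_cor_matrix) <- 1
  }
  if (!isTRUE(all.equal(dim(cross_cor_matrix), c(k, k)))) {
    stop("cross_cor_matrix must be ", k, " x ", k)
  }
  chol_R <- tryCatch(chol(cross_cor_matrix), error = function(e) {
    stop("cross-index correlation matrix is not positive definite")
  })
  if (is.null(noise_sd)) {
    noise_sd <- vapply(regions, function(r) {
      noise_sd_for_r2(r$beta, phi, r$target_r2)
    }, numeric(1))
  }
  stopifnot(all(names(regions) %in% names(noise_sd)))
  structure(list(
    years = as.integer(years), split_year = as.integer(split_year),
    origin = origin, width = width, upper = upper,
    split_latitude = split_latitude,
    pixels_per_band = as.integer(pixels_per_band),
    regions = regions, noise_sd = noise_sd,
    driver_index = driver_index, index_names = index_names,
    phi = phi, chol_R = chol_R, cross_cor_matrix = cross_cor_matrix,
    sst_offset = sst_offset, sst_scale = sst_scale,
    beuti_scale = beuti_scale,
    cloud_prob = cloud_prob, cloud_fraction = cloud_fraction,
    suppression_factor = suppression_factor
  ), class = "scenario_config")
}

#' Generate the monthly index series of a scenario
#'
#' Latent factors are zero-mean unit-variance monthly AR(1) processes with
#' the configured cross-correlation, interpreted as warm-positive thermal
#' anomalies. Indices named `MOCI*` are the latents themselves, `SST*` are
#' `sst_offset + sst_scale * latent` and `BEUTI*` are `-beuti_scale * latent`
#' (upwelling-driven nutrient flux moves against warm anomalies). Months run
#' from January of the year before the first kelp year (so the lagged fall
#' season of the first year exists) through December of the last.
#'
#' @param config A [scenario_config()].
#' @return data.frame `index_name, year, month, value`.
#' @export
gen_monthly_indices <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- seq(min(config$years) - 1L, max(config$years))
  n_months <- 12L * length(years)
  k <- length(config$index_names)
  phi <- config$phi
  # cross-correlated innovations scaled for unit stationary variance
  innov <- matrix(stats::rnorm(n_months * k), n_months, k) %*% config$chol_R
  innov <- innov * sqrt(1 - phi^2)
  init <- as.numeric(stats::rnorm(k) %*% config$chol_R)
  latent <- vapply(seq_len(k), function(j) {
    as.numeric(stats::filter(innov[, j], phi, method = "recursive",
                             init = init[j]))
  }, numeric(n_months))
  out <- lapply(seq_len(k), function(j) {
    nm <- config$index_names[j]
    value <- if (startsWith(nm, "SST")) {
      config$sst_offset + config$sst_scale * latent[, j]
    } else if (startsWith(nm, "BEUTI")) {
      -config$beuti_scale * latent[, j]
    } else {
      latent[, j]
    }
    data.frame(
      index_name = nm,
      year = rep(years, each = 12L),
      month = rep(1:12, length(years)),
      value = value, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Generate the true regional kelp extents of a scenario
#'
#' For each region and kelp year, `truth_km2 = max(0, alpha + beta * w +
#' eps)` where `w` is the winter mean of the driver index and `eps` is
#' Gaussian with the region's noise standard deviation. Truncation at zero is
#' recorded (it is rare under the default calibration).
#'
#' @param config A [scenario_config()].
#' @param indices Output of [gen_monthly_indices()].
#' @return data.frame `region, year, winter_value, eps, truth_km2, truncated`.
#' @export
gen_kelp_truth <- function(config, indices) {
  stopifnot(inherits(config, "scenario_config"))
  winter <- seasonal_predictors(indices, config$years, "winter",
                                config$driver_index)
  if (anyNA(winter$value)) stop("driver index does not cover all winters")
  w <- winter$value[match(config$years, winter$kelp_year)]
  out <- lapply(names(config$regions), function(reg) {
    par <- config$regions[[reg]]
    eps <- stats::rnorm(length(config$years), 0, config$noise_sd[[reg]])
    raw <- par$alpha + par$beta * w + eps
    data.frame(
      region = reg, year = config$years, winter_value = w, eps = eps,
      truth_km2 = pmax(0, raw), truncated = raw < 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Fixed unimodal band-weight profile (kelp patchiness): a discretised
# Gaussian bump over the region's bands, so QC acts non-uniformly.
.band_weights <- function(n_bands) {
  w <- stats::dnorm(seq_len(n_bands), mean = (n_bands + 1) / 2,
                    sd = max(1, n_bands / 4))
  w / sum(w)
}

#' Generate the pixel-level canopy table of a scenario
#'
#' Regional truth is allocated across the region's latitude bands by a fixed
#' unimodal weight profile, and within a band filled into 30x30 m pixels (at
#' most 900 m2 each, so a band holds its area as a run of full pixels plus one
#' partial pixel and observed zeros). Cloud dropout then hits each band-year
#' independently with probability `cloud_prob`, turning a random
#' `cloud_fraction` of that band's pixels into missing values.
#'
#' @param config A [scenario_config()].
#' @param indices Output of [gen_monthly_indices()].
#' @param truth Optional pre-generated [gen_kelp_truth()] table; generated
#'   (consuming RNG) when NULL.
#' @param clouds Set FALSE to disable cloud dropout regardless of config.
#' @return List with `pixels` (data.frame `latitude, longitude, year,
#'   quarter, canopy_area_m2`, NA = cloud-obscured) and `truth`.
#' @export
gen_canopy_pixels <- function(config, indices, truth = NULL, clouds = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(truth)) truth <- gen_kelp_truth(config, indices)
  ppb <- config$pixels_per_band
  edges <- seq(config$origin, config$upper - config$width, by = config$width)
  region_of <- ifelse(edges >= config$split_latitude, "north", "south")
  years <- config$years
  n_years <- length(years)
  pieces <- lapply(names(config$regions), function(reg) {
    bands <- which(region_of == reg)
    n_bands <- length(bands)
    if (n_bands == 0) stop("no latitude bands fall in region '", reg, "'")
    wts <- .band_weights(n_bands)
    tr <- truth[truth$region == reg, , drop = FALSE]
    tv <- tr$truth_km2[match(years, tr$year)] * 1e6   # m2 per region-year
    # band x year target areas, then deterministic pixel fill within bands
    area_by <- outer(wts, tv)                          # n_bands x n_years
    if (any(area_by > 900 * ppb)) {
      stop("band capacity exceeded in region '", reg,
           "': increase pixels_per_band")
    }
    # pixel i (0-based) of a band holds min(900, max(0, A - 900*i))
    pix_idx <- rep(seq_len(ppb) - 1L, times = n_bands * n_years)
    a_rep <- rep(as.numeric(area_by), each = ppb)      # band varies fastest
    area <- pmin(900, pmax(0, a_rep - 900 * pix_idx))
    band_rep <- rep(rep(bands, n_years), each = ppb)
    year_rep <- rep(years, each = ppb * n_bands)
    lat <- config$origin + (band_rep - 1L) * config$width +
      config$width * ((pix_idx + 0.5) / ppb)
    if (clouds && config$cloud_prob > 0 && config$cloud_fraction > 0) {
      hit <- stats::runif(n_bands * n_years) < config$cloud_prob
      n_drop <- round(config$cloud_fraction * ppb)
      if (any(hit) && n_drop > 0) {
        drop_idx <- unlist(lapply(which(hit), function(cell) {
          (cell - 1L) * ppb + sample.int(ppb, n_drop)
        }))
        area[drop_idx] <- NA_real_
      }
    }
    data.frame(
      latitude = lat, longitude = -123.8, year = year_rep, quarter = 3L,
      canopy_area_m2 = area
    )
  })
  list(pixels = do.call(rbind, pieces), truth = truth)
}

#' Apply the post-split suppression regime to a pixel table
#'
#' For years at or after `split_year`, every observed pixel's canopy area is
#' multiplied by `suppression_factor`; the environment is untouched. This is
#' the stand-in for a biotic regime (urchin herbivory) decoupling observed
#' kelp from oceanographic drivers.
#'
#' @param pixels Pixel table from [gen_canopy_pixels()].
#' @param split_year First affected year.
#' @param suppression_factor Multiplier in (0, 1].
#' @return The modified pixel table.
#' @export
apply_collapse_scenario <- function(pixels, split_year, suppression_factor) {
  stopifnot(suppression_factor > 0, suppression_factor <= 1)
  sel <- pixels$year >= split_year & !is.na(pixels$canopy_area_m2)
  pixels$canopy_area_m2[sel] <- pixels$canopy_area_m2[sel] * suppression_factor
  pixels
}

#' Run a whole scenario from a seed
#'
#' Deterministic end-to-end generation: indices, truth, pixels, and (when the
#' configured `suppression_factor` is below 1) the collapse regime. Every
#' output is a pure function of `(config, seed)`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param clouds Set FALSE to disable cloud dropout.
#' @return List with `indices`, `pixels`, `truth` and `config`.
#' @export
simulate_scenario <- function(config, seed, clouds = TRUE) {
  set.seed(seed)
  indices <- gen_monthly_indices(config)
  gen <- gen_canopy_pixels(config, indices, clouds = clouds)
  pixels <- gen$pixels
  if (config$suppression_factor < 1) {
    pixels <- apply_collapse_scenario(pixels, config$split_year,
                                      config$suppression_factor)
  }
  list(indices = indices, pixels = pixels, truth = gen$truth, config = config)
}
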