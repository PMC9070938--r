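# Independent oracles and fixture builders shared across the tests.
# The oracles deliberately avoid the package's code paths: plain
# normal-equations arithmetic, explicit loops, direct distribution calls.

# Closed-form univariate OLS from the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - ybar)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  se_slope <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se_slope
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  aic <- if (sse == 0) -Inf else n * log(2 * pi * sse / n) + n + 2 * 2
  list(slope = slope, intercept = intercept, n = n, r_squared = r2,
       sse = sse, se_slope = se_slope, p_slope = p, aic = aic)
}

# Exhaustive leave-one-out using the closed-form oracle for every refit.
oracle_loo <- function(pairs) {
  n <- nrow(pairs)
  pred <- refit_r2 <- numeric(n)
  for (i in seq_len(n)) {
    o <- oracle_ols(pairs$x[-i], pairs$y[-i])
    pred[i] <- o$intercept + o$slope * pairs$x[i]
    refit_r2[i] <- o$r_squared
  }
  err <- ifelse(pairs$y == 0, NA_real_, abs(pairs$y - pred) / abs(pairs$y) * 100)
  list(predicted = pred, refit_r2 = refit_r2, error_pct = err)
}

# Pixel records for one band-year: one row per element of `areas` (NA = cloud),
# placed mid-band so band assignment is unambiguous.
pixels_for <- function(band_id, year, areas, origin = 38, width = 0.1) {
  data.frame(
    latitude = origin + band_id * width + width / 2,
    longitude = -123.8,
    year = year,
    quarter = 3L,
    canopy_area_m2 = as.numeric(areas)
  )
}

# A fully observed grid: every listed band in every listed year carries
# `n_pixels` pixels of `area` m2 each.
full_grid_pixels <- function(bands, years, n_pixels, area,
                             origin = 38, width = 0.1) {
  do.call(rbind, lapply(bands, function(b) {
    do.call(rbind, lapply(years, function(y) {
      pixels_for(b, y, rep(area, n_pixels), origin, width)
    }))
  }))
}

# Brute-force recomputation of the band QC flags: per-band median over the
# years that have data, strict "< fraction * median" rule, absent band-years
# flagged. Returns a data.frame keyed like flag_band_years().
oracle_flags <- function(summaries, qc_fraction, years) {
  bands <- sort(unique(summaries$band_id))
  out <- expand.grid(band_id = bands, year = as.integer(years),
                     KEEP.OUT.ATTRS = FALSE)
  out$flagged <- NA
  for (r in seq_len(nrow(out))) {
    b <- out$band_id[r]
    counts <- summaries$n_data_pixels[summaries$band_id == b]
    med <- stats::median(counts)
    row <- summaries[summaries$band_id == b & summaries$year == out$year[r], ]
    out$flagged[r] <- if (nrow(row) == 0) TRUE else {
      row$n_data_pixels < qc_fraction * med
    }
  }
  out[order(out$band_id, out$year), ]
}

# Direct draw of regression pairs from the calibrated linear world, without
# the pixel/aggregation machinery: x is a winter-mean-like Gaussian.
draw_pairs <- function(n, alpha, beta, noise_sd, x_sd = 1) {
  x <- stats::rnorm(n, 0, x_sd)
  y <- alpha + beta * x + stats::rnorm(n, 0, noise_sd)
  data.frame(kelp_year = seq_len(n) + 1990L, x = x, y = y)
}
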