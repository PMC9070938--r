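# The synthetic-data generator: index model, kelp link, pixel allocation,
# cloud dropout and the collapse regime.

small_cfg <- function(...) {
  scenario_config(
    years = 1995:2004, split_year = 2001, pixels_per_band = 120,
    regions = list(north = list(alpha = 0.2, beta = -0.05, target_r2 = 0.8),
                   south = list(alpha = 0.3, beta = -0.05, target_r2 = 0.8)),
    index_names = c("MOCI_south", "SST_N14", "BEUTI_37N"),
    driver_index = "MOCI_south", ...
  )
}

test_that("every generator output is a pure function of (config, seed)", {
  cfg <- small_cfg()
  a <- simulate_scenario(cfg, seed = 5)
  b <- simulate_scenario(cfg, seed = 5)
  expect_identical(a$indices, b$indices)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
  c <- simulate_scenario(cfg, seed = 6)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("monthly series have the configured persistence structure", {
  # phi = 0: lag-1 autocorrelation within sampling error of zero
  cfg <- scenario_config(years = 1001:4360, phi = 0,
                         index_names = "MOCI_south",
                         regions = list(north = list(alpha = 1, beta = -0.1,
                                                     target_r2 = 0.5)))
  set.seed(101)
  ix <- gen_monthly_indices(cfg)
  v <- ix$value
  expect_gt(length(v), 1e4)
  expect_lt(abs(stats::cor(v[-1], v[-length(v)])), 0.02)
  expect_lt(abs(mean(v)), 0.03)
  expect_lt(abs(stats::sd(v) - 1), 0.03)

  # a configured winter-spring correlation of 0.8 is realised empirically
  cfg <- scenario_config(years = 1001:1200, season_cor = 0.8,
                         index_names = "MOCI_south",
                         regions = list(north = list(alpha = 1, beta = -0.1,
                                                     target_r2 = 0.5)))
  set.seed(102)
  ix <- gen_monthly_indices(cfg)
  sp <- seasonal_predictors(ix, 1001:1200, c("winter", "spring"))
  w <- sp$value[sp$season == "winter"]
  s <- sp$value[sp$season == "spring"]
  expect_lt(abs(stats::cor(w, s) - 0.8), 0.1)
})

test_that("index transforms follow the field's sign conventions", {
  cfg <- scenario_config(
    years = 1981:2004, cross_cor = 0.9,
    index_names = c("MOCI_south", "SST_N14", "BEUTI_37N"),
    regions = list(north = list(alpha = 0.2, beta = -0.05, target_r2 = 0.8))
  )
  set.seed(103)
  ix <- gen_monthly_indices(cfg)
  wide <- split(ix$value, ix$index_name)
  # SST rides the warm anomaly; BEUTI (upwelling nutrients) opposes it
  expect_gt(stats::cor(wide$MOCI_south, wide$SST_N14), 0.5)
  expect_lt(stats::cor(wide$MOCI_south, wide$BEUTI_37N), -0.5)
  expect_gt(mean(wide$SST_N14), 10)  # degrees C, not an anomaly
})

test_that("cross-index correlation is honoured and validated", {
  cfg <- scenario_config(years = 1001:1150, cross_cor = 0.6, phi = 0,
                         index_names = c("MOCI_south", "MOCI_north"))
  set.seed(104)
  ix <- gen_monthly_indices(cfg)
  wide <- split(ix$value, ix$index_name)
  expect_lt(abs(stats::cor(wide$MOCI_south, wide$MOCI_north) - 0.6), 0.05)
  expect_error(
    scenario_config(index_names = c("a", "b"), driver_index = "a",
                    cross_cor_matrix = matrix(c(1, 2, 2, 1), 2)),
    "positive definite"
  )
})

test_that("noiseless cloud-free pixels round-trip through the aggregation", {
  cfg <- small_cfg(noise_sd = c(north = 0, south = 0))
  sc <- simulate_scenario(cfg, seed = 7, clouds = FALSE)
  agg <- aggregate_canopy(sc$pixels, years = cfg$years)
  for (reg in c("north", "south")) {
    tr <- sc$truth[sc$truth$region == reg, ]
    a <- agg[agg$region == reg, ]
    expect_lt(max(abs(a$extent_km2 - tr$truth_km2[match(a$year, tr$year)])),
              1e-9)
  }
})

test_that("cloud dropout removes the configured pixel fraction", {
  cfg <- scenario_config(
    years = 2000, pixels_per_band = 100,
    regions = list(north = list(alpha = 0.05, beta = -0.01, target_r2 = 0.5)),
    cloud_prob = 1, cloud_fraction = 0.5, index_names = "MOCI_south"
  )
  set.seed(105)
  ix <- gen_monthly_indices(cfg)
  gen <- gen_canopy_pixels(cfg, ix)
  s <- summarize_band_years(gen$pixels)
  expect_true(all(s$n_data_pixels == 50L))
})

test_that("band capacity violations are a configuration error", {
  cfg <- scenario_config(
    years = 2000, pixels_per_band = 3,
    regions = list(north = list(alpha = 5, beta = 0, target_r2 = NULL)),
    noise_sd = c(north = 0), index_names = "MOCI_south"
  )
  set.seed(106)
  ix <- gen_monthly_indices(cfg)
  expect_error(gen_canopy_pixels(cfg, ix), "pixels_per_band")
})

test_that("the collapse scenario scales observed canopy only after the split", {
  cfg <- small_cfg()
  sc <- simulate_scenario(cfg, seed = 8, clouds = FALSE)
  same <- apply_collapse_scenario(sc$pixels, cfg$split_year, 1)
  expect_identical(same, sc$pixels)
  supp <- apply_collapse_scenario(sc$pixels, cfg$split_year, 0.1)
  agg0 <- aggregate_canopy(sc$pixels, years = cfg$years)
  agg1 <- aggregate_canopy(supp, years = cfg$years)
  pre <- agg0$year < cfg$split_year
  expect_equal(agg1$extent_km2[pre], agg0$extent_km2[pre])
  expect_equal(agg1$extent_km2[!pre], 0.1 * agg0$extent_km2[!pre],
               tolerance = 1e-12)
  expect_error(apply_collapse_scenario(sc$pixels, 2001, 0), "suppression")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(scenario_config(phi = 1.2), "phi")
  expect_error(scenario_config(cloud_prob = 2), "cloud_prob")
  expect_error(scenario_config(suppression_factor = 0), "suppression")
  expect_error(scenario_config(driver_index = "nope"), "driver_index")
})
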