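# Band assignment, band-year summaries, QC flags and regional aggregation.

test_that("latitude bands are half-open 0.1-degree intervals from the origin", {
  expect_identical(assign_latitude_band(38.0), 0L)
  expect_identical(assign_latitude_band(38.15), 1L)
  # the split latitude belongs to the band above it: 39.00 N is the first
  # northern band under the half-open convention
  expect_identical(assign_latitude_band(39.0), 10L)
  expect_identical(assign_latitude_band(c(38.05, 39.95)), c(0L, 19L))
  expect_error(assign_latitude_band(40.0), "domain")
  expect_error(assign_latitude_band(37.99), "domain")
})

test_that("band-year summaries count observed pixels only", {
  # a 900 m2 pixel, an observed zero, and a cloud-obscured pixel
  px <- pixels_for(0, 2000, c(900, 0, NA))
  s <- summarize_band_years(px)
  expect_equal(s$n_data_pixels, 2L)
  expect_equal(s$area_sum, 900)

  # 2 bands x 2 years, 4 pixels of 10 m2 each, all observed
  grid <- full_grid_pixels(bands = 0:1, years = 2000:2001, n_pixels = 4,
                           area = 10)
  s <- summarize_band_years(grid)
  expect_equal(nrow(s), 4L)
  expect_true(all(s$n_data_pixels == 4L))
  expect_true(all(s$area_sum == 40))

  # a band-year whose pixels are all missing is not summarised
  px <- rbind(pixels_for(0, 2000, c(1, 2)), pixels_for(0, 2001, c(NA, NA)))
  s <- summarize_band_years(px)
  expect_equal(s$year, 2000L)

  expect_equal(nrow(summarize_band_years(px[0, ])), 0L)
})

test_that("band flags use a strict 90%-of-median rule", {
  mk <- function(counts, band = 0L) {
    do.call(rbind, lapply(seq_along(counts), function(i) {
      data.frame(band_id = band, year = 1990L + i,
                 n_data_pixels = counts[i], area_sum = counts[i] * 1)
    }))
  }
  # median 100, threshold 90: 89 flags, 100 does not
  fl <- flag_band_years(mk(c(100, 100, 100, 89)))
  expect_equal(fl$flagged, c(FALSE, FALSE, FALSE, TRUE))
  # boundary: a count of exactly 90 is NOT below 90% of the median
  fl <- flag_band_years(mk(c(100, 100, 90)))
  expect_false(any(fl$flagged))
  # a single-year band is its own median
  fl <- flag_band_years(mk(5))
  expect_false(fl$flagged)
  # even number of years: median is the mean of the middle two
  fl <- flag_band_years(mk(c(80, 100, 104, 120)))  # median 102, threshold 91.8
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE, FALSE))

  expect_error(flag_band_years(mk(c(1, 2)), qc_fraction = 0), "qc_fraction")
  expect_error(flag_band_years(mk(c(1, 2)), qc_fraction = 1.1), "qc_fraction")
})

test_that("a region-year is missing when flagged bands exceed the tolerance", {
  # 10 southern bands, constant 100-pixel coverage except band 0 and 1 in 1996
  px <- full_grid_pixels(0:9, 1995:1997, n_pixels = 10, area = 1000 / 10)
  # remove 2 of 10 pixels in bands 0 and 1 during 1996 (count 8 < 9 = 90% of 10)
  idx <- which(px$year == 1996 & assign_latitude_band(px$latitude) <= 1)
  px$canopy_area_m2[idx[seq_along(idx) %% 10 < 2]] <- NA
  s <- summarize_band_years(px)
  fl <- flag_band_years(s)
  expect_equal(sum(fl$flagged[fl$year == 1996]), 2L)
  agg <- aggregate_regional_series(s, fl)
  south <- agg[agg$region == "south", ]
  expect_true(is.na(south$extent_km2[south$year == 1996]))
  expect_equal(south$missing_band_fraction[south$year == 1996], 0.2)
  expect_equal(south$flagged_bands[south$year == 1996], "0;1")
  expect_false(anyNA(south$extent_km2[south$year != 1996]))
})

test_that("a fully observed grid conserves total area through aggregation", {
  # 10 bands x 1e5 m2 each -> 1.0 km2 per year
  px <- full_grid_pixels(0:9, 2000:2004, n_pixels = 112, area = 1e5 / 112)
  agg <- aggregate_canopy(px)
  south <- agg[agg$region == "south", ]
  expect_equal(south$extent_km2, rep(1.0, 5), tolerance = 1e-12)
  # brute-force pixel sum matches to < 1e-9 km2
  expect_lt(max(abs(south$extent_km2 -
                      sum(px$canopy_area_m2[px$year == 2000]) * 1e-6)), 1e-9)
})

test_that("relaxing QC settings never turns a present year missing", {
  set.seed(42)
  for (rep in 1:10) {
    px <- full_grid_pixels(0:4, 2000:2006, n_pixels = 20, area = 50)
    px$canopy_area_m2[sample(nrow(px), 120)] <- NA
    s <- summarize_band_years(px)
    base <- aggregate_canopy(px, qc_fraction = 0.9, tolerance = 0.1)
    looser_qc <- aggregate_canopy(px, qc_fraction = 0.7, tolerance = 0.1)
    looser_tol <- aggregate_canopy(px, qc_fraction = 0.9, tolerance = 0.3)
    present <- !is.na(base$extent_km2)
    expect_true(all(!is.na(looser_qc$extent_km2[present])))
    expect_true(all(!is.na(looser_tol$extent_km2[present])))
  }
})

test_that("bands partition into regions and the split conserves total area", {
  px <- full_grid_pixels(0:19, 2000:2002, n_pixels = 5, area = 100)
  s <- summarize_band_years(px)
  fl <- flag_band_years(s)
  at39 <- aggregate_regional_series(s, fl, split_latitude = 39.0)
  at392 <- aggregate_regional_series(s, fl, split_latitude = 39.2)
  tot <- function(a) tapply(a$extent_km2, a$year, sum)
  expect_equal(tot(at39), tot(at392), tolerance = 1e-12)
  # the two bands between 39.0 and 39.2 moved from north to south
  n39 <- at39$extent_km2[at39$region == "north" & at39$year == 2000]
  n392 <- at392$extent_km2[at392$region == "north" & at392$year == 2000]
  expect_equal(n39 - n392, 2 * 5 * 100 * 1e-6, tolerance = 1e-12)
})

test_that("flags match a brute-force oracle on random small fixtures", {
  set.seed(7)
  for (rep in 1:20) {
    n_bands <- sample(2:5, 1)
    years <- 2000:(1999 + sample(4:10, 1))
    counts <- matrix(sample(c(0, 5:30), n_bands * length(years), TRUE),
                     n_bands, length(years))
    s <- do.call(rbind, lapply(seq_len(n_bands), function(b) {
      do.call(rbind, lapply(seq_along(years), function(j) {
        if (counts[b, j] == 0) return(NULL)
        data.frame(band_id = b - 1L, year = years[j],
                   n_data_pixels = counts[b, j], area_sum = counts[b, j] * 10)
      }))
    }))
    frac <- stats::runif(1, 0.5, 1)
    got <- flag_band_years(s, frac, years)
    want <- oracle_flags(s, frac, years)
    expect_equal(got$flagged, want$flagged)
  }
})

test_that("aggregation rejects bad configuration and empty regions", {
  px <- full_grid_pixels(0:3, 2000, n_pixels = 2, area = 10)  # south only
  s <- summarize_band_years(px)
  fl <- flag_band_years(s)
  expect_error(aggregate_regional_series(s, fl, tolerance = 1), "tolerance")
  # requesting a region with no bands names the region
  expect_error(aggregate_regional_series(s, fl, regions = c("north", "south")),
               "north")
  # by default only the populated region is reported
  agg <- aggregate_regional_series(s, fl)
  expect_equal(unique(agg$region), "south")
})
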