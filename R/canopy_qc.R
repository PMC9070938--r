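# Quality control and regional aggregation of satellite kelp-canopy pixels.
#
# The upstream Landsat product cannot distinguish a cloud-obscured pixel from a
# pixel with zero kelp, so regional sums are only trusted when enough pixels
# report data. QC works on 0.1-degree latitude bands: a band-year with fewer
# data pixels than 90% of that band's across-year median is flagged missing,
# and a region-year with more than 10% of its bands flagged is itself missing.

#' Assign a latitude to a 0.1-degree band
#'
#' Bands are half-open intervals `[origin + k*width, origin + (k+1)*width)`,
#' indexed from 0 at `origin`. The split latitude between regions (39 N, Point
#' Arena) therefore belongs to the first band of the northern region.
#'
#' @param latitude Numeric vector, decimal degrees north.
#' @param origin Southern edge of the study domain (degrees N). Default 38.
#' @param width Band width in degrees. Default 0.1.
#' @param upper Northern (exclusive) edge of the study domain. Default 40.
#' @return Integer vector of band indices (0-based).
#' @examples
#' assign_latitude_band(c(38.0, 38.15, 39.0))
#' @export
assign_latitude_band <- function(latitude, origin = 38, width = 0.1, upper = 40) {
  stopifnot(is.numeric(latitude), width > 0, upper > origin)
  bad <- !is.na(latitude) & (latitude < origin | latitude >= upper)
  if (any(bad)) {
    stop(sprintf(
      "latitude outside study domain [%g, %g): e.g. %g",
      origin, upper, latitude[which(bad)[1]]
    ))
  }
  as.integer(floor((latitude - origin) / width))
}

#' Read a pixel-level canopy CSV
#'
#' Expected header: `latitude,longitude,year,quarter,canopy_area_m2`; an empty
#' `canopy_area_m2` field means the pixel was not observed (cloud/QC), which is
#' distinct from an observed zero.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with those five columns; `canopy_area_m2` is NA where
#'   the field was empty.
#' @export
read_canopy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("latitude", "longitude", "year", "quarter", "canopy_area_m2")
  if (!all(need %in% names(df))) {
    stop(
      "canopy CSV must have columns: ", paste(need, collapse = ", ")
    )
  }
  df$canopy_area_m2 <- as.numeric(df$canopy_area_m2)
  df
}

#' Sum canopy area per band-year
#'
#' Restricts to one quarter (Q3, July-September, for the summer canopy peak),
#' assigns each pixel to its latitude band, and for every (band, year) with at
#' least one observed pixel reports the number of data pixels and their summed
#' area. Observed zero-kelp pixels count as data; NA pixels do not.
#'
#' @param pixels data.frame with columns `latitude`, `year`, `quarter`,
#'   `canopy_area_m2` (NA = not observed).
#' @param quarter Which quarter to keep (integer 1-4). Default 3.
#' @inheritParams assign_latitude_band
#' @return data.frame `band_id, year, n_data_pixels, area_sum` (m2), one row
#'   per band-year with data, ordered by band then year. Empty input gives an
#'   empty frame.
#' @export
summarize_band_years <- function(pixels, quarter = 3L, origin = 38, width = 0.1,
                                 upper = 40) {
  stopifnot(is.data.frame(pixels))
  empty <- data.frame(
    band_id = integer(), year = integer(),
    n_data_pixels = integer(), area_sum = numeric()
  )
  if (nrow(pixels) == 0) return(empty)
  px <- pixels[pixels$quarter == quarter, , drop = FALSE]
  px <- px[!is.na(px$canopy_area_m2), , drop = FALSE]
  if (nrow(px) == 0) return(empty)
  if (any(px$canopy_area_m2 < 0 | px$canopy_area_m2 > 900)) {
    stop("canopy_area_m2 must lie in [0, 900] m2 for a 30x30 m pixel")
  }
  band <- assign_latitude_band(px$latitude, origin, width, upper)
  # numeric key band*1e5 + year keeps rowsum vectorised on large pixel tables
  key <- band * 1e5 + px$year
  sums <- rowsum(cbind(n = 1, area = px$canopy_area_m2), key)
  ids <- as.numeric(rownames(sums))
  out <- data.frame(
    band_id = as.integer(ids %/% 1e5),
    year = as.integer(ids %% 1e5),
    n_data_pixels = as.integer(sums[, "n"]),
    area_sum = as.numeric(sums[, "area"]),
    row.names = NULL
  )
  out[order(out$band_id, out$year), , drop = FALSE]
}

#' Flag band-years with too few data pixels
#'
#' For each band, the median number of data pixels across all years with a
#' summary is the reference; a band-year is flagged missing iff its pixel
#' count is strictly below `qc_fraction` times that median (a count exactly at
#' 90% of the median is kept). Band-years present in `years` but absent from
#' the summaries are flagged missing with a count of 0.
#'
#' @param summaries Output of [summarize_band_years()].
#' @param qc_fraction Fraction of the band median below which a band-year is
#'   flagged. Default 0.9.
#' @param years Integer vector of years the analysis covers; defaults to the
#'   observed year range of `summaries`.
#' @return data.frame `band_id, year, n_data_pixels, band_median, flagged`
#'   covering every (band, year) combination.
#' @export
flag_band_years <- function(summaries, qc_fraction = 0.9, years = NULL) {
  if (!(qc_fraction > 0 && qc_fraction <= 1)) {
    stop("qc_fraction must lie in (0, 1]")
  }
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  if (is.null(years)) years <- seq(min(summaries$year), max(summaries$year))
  bands <- sort(unique(summaries$band_id))
  grid <- expand.grid(band_id = bands, year = as.integer(years),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, summaries[, c("band_id", "year", "n_data_pixels")],
                by = c("band_id", "year"), all.x = TRUE)
  grid$n_data_pixels[is.na(grid$n_data_pixels)] <- 0L
  med <- tapply(summaries$n_data_pixels, summaries$band_id, stats::median)
  grid$band_median <- as.numeric(med[as.character(grid$band_id)])
  grid$flagged <- grid$n_data_pixels < qc_fraction * grid$band_median
  grid[order(grid$band_id, grid$year), , drop = FALSE]
}

#' Aggregate flagged band-years into regional canopy series
#'
#' Bands are split into `south` and `north` regions by their lower edge
#' relative to `split_latitude` (half-open, so a band starting exactly at the
#' split is northern). For each region-year the missing-band fraction is the
#' number of flagged bands over the number of active bands in the region
#' (bands with at least one summary); if it exceeds `tolerance` the year is
#' missing, otherwise the extent is the sum of unflagged band areas converted
#' to km2 (no infilling of flagged bands).
#'
#' @param summaries Output of [summarize_band_years()].
#' @param flags Output of [flag_band_years()].
#' @param split_latitude Boundary between regions, degrees N. Default 39
#'   (Point Arena).
#' @param tolerance Maximum tolerated missing-band fraction. Default 0.1.
#' @inheritParams assign_latitude_band
#' @param years Years to report; defaults to the flag table's years.
#' @param regions Which regions to report; default the regions that have at
#'   least one band in the data. Requesting a region with no bands is an
#'   error.
#' @return data.frame `region, year, extent_km2, missing_band_fraction,
#'   flagged_bands` with `extent_km2` NA for missing years and
#'   `flagged_bands` a `;`-separated list of flagged band ids (the QC log).
#' @export
aggregate_regional_series <- function(summaries, flags, split_latitude = 39,
                                      tolerance = 0.1, origin = 38, width = 0.1,
                                      years = NULL, regions = NULL) {
  if (!(tolerance >= 0 && tolerance < 1)) stop("tolerance must lie in [0, 1)")
  if (is.null(years)) years <- sort(unique(flags$year))
  lower_edge <- origin + flags$band_id * width
  flags$region <- ifelse(lower_edge >= split_latitude, "north", "south")
  if (is.null(regions)) regions <- intersect(c("north", "south"), flags$region)
  if (length(regions) == 0) stop("no latitude bands in any region")
  for (reg in regions) {
    if (!any(flags$region == reg)) {
      stop(sprintf("no latitude bands fall in the '%s' region", reg))
    }
  }
  sm <- merge(flags, summaries[, c("band_id", "year", "area_sum")],
              by = c("band_id", "year"), all.x = TRUE)
  sm$area_sum[is.na(sm$area_sum)] <- 0
  out <- do.call(rbind, lapply(regions, function(reg) {
    fr <- sm[sm$region == reg, , drop = FALSE]
    n_active <- length(unique(fr$band_id))
    do.call(rbind, lapply(as.integer(years), function(yr) {
      fy <- fr[fr$year == yr, , drop = FALSE]
      flagged <- fy$band_id[fy$flagged]
      frac <- length(flagged) / n_active
      extent <- if (frac > tolerance) NA_real_ else {
        sum(fy$area_sum[!fy$flagged]) * 1e-6
      }
      data.frame(
        region = reg, year = yr, extent_km2 = extent,
        missing_band_fraction = frac,
        flagged_bands = paste(sort(flagged), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pixel table to regional series in one step
#'
#' Convenience wrapper chaining [summarize_band_years()], [flag_band_years()]
#' and [aggregate_regional_series()] with shared geometry arguments.
#'
#' @inheritParams summarize_band_years
#' @inheritParams flag_band_years
#' @inheritParams aggregate_regional_series
#' @return See [aggregate_regional_series()].
#' @export
aggregate_canopy <- function(pixels, quarter = 3L, origin = 38, width = 0.1,
                             upper = 40, split_latitude = 39, qc_fraction = 0.9,
                             tolerance = 0.1, years = NULL, regions = NULL) {
  summaries <- summarize_band_years(pixels, quarter, origin, width, upper)
  if (nrow(summaries) == 0) {
    stop("aggregation: no observed pixels in the requested quarter")
  }
  flags <- flag_band_years(summaries, qc_fraction, years)
  aggregate_regional_series(summaries, flags, split_latitude, tolerance,
                            origin, width, years, regions)
}
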