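# Seasonal predictors from monthly ocean-index series.
#
# Kelp canopy peaks in summer (Q3); candidate drivers are seasonal means of
# monthly indices aligned to that "kelp year": winter = JFM and spring = AMJ of
# the same calendar year, summer = JAS concurrent with the canopy, and fall is
# OND of the *previous* calendar year (the season preceding winter).

.season_table <- list(
  fall_prev = list(months = 10:12, year_offset = -1L),
  winter    = list(months = 1:3,   year_offset = 0L),
  spring    = list(months = 4:6,   year_offset = 0L),
  summer    = list(months = 7:9,   year_offset = 0L)
)

#' Season names understood by the package
#' @return Character vector `c("fall_prev", "winter", "spring", "summer")`.
#' @export
season_names <- function() names(.season_table)

#' Read a monthly index CSV
#'
#' Expected header: `index_name,year,month,value`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with those four columns.
#' @export
read_index_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index_name", "year", "month", "value")
  if (!all(need %in% names(df))) {
    stop("index CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Seasonal mean of a monthly series for one kelp year
#'
#' The mean of the season's three monthly values; `fall_prev` uses
#' October-December of `kelp_year - 1`. If any of the three months is absent
#' the season is missing (NA) -- no partial means.
#'
#' @param indices data.frame `index_name, year, month, value`.
#' @param index_name Which index to average.
#' @param season One of [season_names()].
#' @param kelp_year Calendar year of the summer canopy observation.
#' @return A single numeric value, NA if the season is incomplete.
#' @export
seasonal_average <- function(indices, index_name, season, kelp_year) {
  if (!season %in% names(.season_table)) {
    stop("unknown season: ", season)
  }
  sp <- .season_table[[season]]
  yr <- kelp_year + sp$year_offset
  sub <- indices[indices$index_name == index_name &
                   indices$year == yr &
                   indices$month %in% sp$months, , drop = FALSE]
  if (anyDuplicated(sub$month)) {
    stop("duplicate (year, month) values for index ", index_name)
  }
  if (nrow(sub) < 3L || anyNA(sub$value)) return(NA_real_)
  mean(sub$value)
}

#' Build the full table of seasonal predictors
#'
#' One row per (index, season, kelp year).
#'
#' @inheritParams seasonal_average
#' @param kelp_years Integer vector of kelp years to cover.
#' @param seasons Subset of [season_names()]; default all four.
#' @param index_names Which indices; default all present in `indices`.
#' @return data.frame `index_name, season, kelp_year, value` (value NA where
#'   a season is incomplete).
#' @export
seasonal_predictors <- function(indices, kelp_years,
                                seasons = season_names(),
                                index_names = NULL) {
  if (is.null(index_names)) index_names <- unique(indices$index_name)
  grid <- expand.grid(
    index_name = index_names, season = seasons,
    kelp_year = as.integer(kelp_years),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # vectorised equivalent of seasonal_average over the whole grid: tag each
  # monthly record with its (season, kelp_year) and take 3-month means
  tagged <- do.call(rbind, lapply(seasons, function(se) {
    sp <- .season_table[[se]]
    sub <- indices[indices$index_name %in% index_names &
                     indices$month %in% sp$months, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(index_name = sub$index_name, season = se,
               kelp_year = sub$year - sp$year_offset, value = sub$value,
               stringsAsFactors = FALSE)
  }))
  means <- if (is.null(tagged) || nrow(tagged) == 0) NULL else {
    key <- paste(tagged$index_name, tagged$season, tagged$kelp_year, sep = "\r")
    agg <- rowsum(cbind(n = 1, sum = tagged$value), key)
    if (any(agg[, "n"] > 3L)) {
      stop("duplicate (index, year, month) values in the monthly series")
    }
    data.frame(key = rownames(agg), n = agg[, "n"], sum = agg[, "sum"],
               stringsAsFactors = FALSE)
  }
  gkey <- paste(grid$index_name, grid$season, grid$kelp_year, sep = "\r")
  idx <- match(gkey, means$key)
  grid$value <- ifelse(!is.na(idx) & means$n[idx] == 3L,
                       means$sum[idx] / 3, NA_real_)
  grid[order(grid$index_name, grid$season, grid$kelp_year), , drop = FALSE]
}

#' Join a kelp series with a predictor into complete-case pairs
#'
#' Keeps exactly the years where both the kelp extent and the predictor value
#' are present, in ascending year order. Missingness on either side (QC'd-out
#' kelp years, incomplete seasons) drops the year.
#'
#' @param kelp data.frame with columns `year` and `extent_km2` (NA = missing).
#' @param predictor data.frame with columns `kelp_year` and `value`.
#' @param year_range Optional integer vector restricting the years considered.
#' @return data.frame `kelp_year, x, y` (x = predictor, y = extent in km2).
#' @export
build_pairs <- function(kelp, predictor, year_range = NULL) {
  stopifnot(all(c("year", "extent_km2") %in% names(kelp)),
            all(c("kelp_year", "value") %in% names(predictor)))
  m <- merge(
    data.frame(kelp_year = kelp$year, y = kelp$extent_km2),
    data.frame(kelp_year = predictor$kelp_year, x = predictor$value),
    by = "kelp_year"
  )
  if (!is.null(year_range)) m <- m[m$kelp_year %in% year_range, , drop = FALSE]
  m <- m[is.finite(m$x) & is.finite(m$y), c("kelp_year", "x", "y")]
  m <- m[order(m$kelp_year), , drop = FALSE]
  rownames(m) <- NULL
  m
}
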