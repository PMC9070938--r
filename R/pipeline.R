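# End-to-end orchestration: QC/aggregation -> seasonal join -> screening ->
# selection -> leave-one-out validation -> pre-collapse-trained forecasting.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

.equation_string <- function(region, fit_row) {
  reg <- paste0(toupper(substring(region, 1, 1)), substring(region, 2))
  sign <- if (fit_row$slope < 0) "-" else "+"
  sprintf("%s Kelp = %.2f %s %.2f * %s %s", reg, fit_row$intercept, sign,
          abs(fit_row$slope), fit_row$season, fit_row$index_name)
}

#' Run the full analysis pipeline
#'
#' Executes every stage over a pixel-level canopy table and a monthly index
#' table: regional QC/aggregation, seasonal predictor construction, the
#' regression screen over all (region, index, season) candidates on the
#' pre-collapse years, AIC selection of the best model per region,
#' leave-one-out validation of the selected models, and out-of-period
#' forecasts for the post-collapse years. Also reports the between-region
#' Pearson correlation and winter linear trends of every index over the
#' training years. Deterministic: identical inputs give identical outputs.
#'
#' @param canopy Pixel data.frame (see [read_canopy_csv()]) or a path to such
#'   a CSV.
#' @param indices Monthly index data.frame (see [read_index_csv()]) or a path.
#' @param pre_years Training (pre-collapse) kelp years. Default 1991:2013.
#' @param post_years Forecast (post-collapse) years. Default 2014:2020.
#' @param alpha Significance level for the screen. Default 0.05.
#' @inheritParams aggregate_canopy
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV plus a `run_log.txt`, and partial outputs are removed on failure.
#' @return List with `regional_series`, `predictors`, `screen`, `models`
#'   (one selected row per region with equation string), `fits` (the
#'   refitted `ols_fit` objects), `loo` (per region), `forecast` (one table,
#'   all regions), `region_correlation` and `winter_trends`.
#' @export
run_full_analysis <- function(canopy, indices,
                              pre_years = 1991:2013, post_years = 2014:2020,
                              alpha = 0.05, quarter = 3L,
                              origin = 38, width = 0.1, upper = 40,
                              split_latitude = 39, qc_fraction = 0.9,
                              tolerance = 0.1, out_dir = NULL) {
  if (is.character(canopy)) canopy <- .stage("read", read_canopy_csv(canopy))
  if (is.character(indices)) indices <- .stage("read", read_index_csv(indices))
  years <- sort(c(pre_years, post_years))

  series <- .stage("aggregate", {
    if (nrow(canopy) == 0) stop("canopy table is empty")
    aggregate_canopy(canopy, quarter, origin, width, upper, split_latitude,
                     qc_fraction, tolerance, years)
  })

  predictors <- .stage("seasons", seasonal_predictors(indices, years))

  screen <- .stage("screen",
                   screen_models(series, predictors, alpha, pre_years))

  regions <- unique(series$region)
  models <- list(); fits <- list(); loo <- list(); fc <- list()
  for (reg in regions) {
    sel <- .stage("fit", select_model(screen[screen$region == reg, ]))
    if (is.null(sel)) next
    pred <- predictors[predictors$index_name == sel$index_name &
                         predictors$season == sel$season, ]
    pairs <- build_pairs(series[series$region == reg, ], pred, pre_years)
    fit <- .stage("fit", fit_ols(pairs))
    loo_rep <- .stage("validate", loo_cross_validate(pairs))
    fc_tab <- .stage("forecast", {
      post_pred <- pred[pred$kelp_year %in% post_years, ]
      tab <- forecast_years(fit, post_pred, data.frame(
        year = series$year[series$region == reg],
        extent_km2 = series$extent_km2[series$region == reg]
      ))
      cbind(region = reg, index_name = sel$index_name, season = sel$season,
            tab, stringsAsFactors = FALSE)
    })
    sel$equation <- .equation_string(reg, sel)
    sel$loo_mean_r2 <- loo_rep$mean_refit_r_squared
    sel$loo_mean_error_pct <- loo_rep$mean_error_pct
    sel$loo_sd_error_pct <- loo_rep$sd_error_pct
    models[[reg]] <- sel
    fits[[reg]] <- fit
    loo[[reg]] <- loo_rep
    fc[[reg]] <- fc_tab
  }
  model_table <- if (length(models)) do.call(rbind, models) else NULL
  if (!is.null(model_table)) rownames(model_table) <- NULL
  forecast_table <- if (length(fc)) do.call(rbind, fc) else NULL
  if (!is.null(forecast_table)) rownames(forecast_table) <- NULL

  region_cor <- if (length(regions) == 2) {
    a <- series[series$region == regions[1], ]
    b <- series[series$region == regions[2], ]
    yy <- intersect(a$year, b$year)
    tryCatch(
      pearson_correlation(a$extent_km2[match(yy, a$year)],
                          b$extent_km2[match(yy, b$year)]),
      error = function(e) NULL
    )
  } else NULL

  winter_trends <- .stage("trends", {
    wt <- predictors[predictors$season == "winter" &
                       predictors$kelp_year %in% pre_years, ]
    do.call(rbind, lapply(split(wt, wt$index_name), function(d) {
      tt <- linear_trend_test(d$kelp_year, d$value)
      data.frame(index_name = d$index_name[1], slope_per_year = tt$slope,
                 p = tt$p, n = tt$n, stringsAsFactors = FALSE)
    }))
  })
  rownames(winter_trends) <- NULL

  report <- list(
    regional_series = series, predictors = predictors, screen = screen,
    models = model_table, fits = fits, loo = loo,
    forecast = forecast_table, region_correlation = region_cor,
    winter_trends = winter_trends
  )
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    written <<- c(written, path)
  }
  tryCatch({
    wr(report$regional_series, "regional_series.csv")
    wr(report$predictors, "seasonal_predictors.csv")
    wr(report$screen, "screen_table.csv")
    if (!is.null(report$models)) {
      wr(report$models[, c("region", "equation", "r_squared", "p", "aic", "n",
                           "loo_mean_r2", "loo_mean_error_pct",
                           "loo_sd_error_pct")], "model_table.csv")
    }
    loo_tab <- do.call(rbind, lapply(names(report$loo), function(reg) {
      cbind(region = reg, report$loo[[reg]]$per_year, stringsAsFactors = FALSE)
    }))
    wr(loo_tab, "loo_table.csv")
    wr(report$forecast, "forecast_table.csv")
    wr(report$winter_trends, "winter_trends.csv")
    log_path <- file.path(out_dir, "run_log.txt")
    lines <- c(
      sprintf("rows regional_series: %d", nrow(report$regional_series)),
      sprintf("rows predictors: %d", nrow(report$predictors)),
      sprintf("rows screen: %d", nrow(report$screen)),
      sprintf("models selected: %d",
              if (is.null(report$models)) 0L else nrow(report$models)),
      if (!is.null(report$region_correlation)) {
        sprintf("between-region correlation: rho = %.3f (p = %.3g, n = %d)",
                report$region_correlation$rho, report$region_correlation$p,
                report$region_correlation$n)
      }
    )
    writeLines(lines, log_path)
    written <- c(written, log_path)
  }, error = function(e) {
    unlink(written)
    stop("stage 'write': ", conditionMessage(e), call. = FALSE)
  })
  invisible(written)
}
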