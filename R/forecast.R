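# Forecasting from models trained on the pre-collapse period.

#' Predict kelp extent for years outside the training period
#'
#' Applies a fitted model to predictor values for forecast years and compares
#' against observations where available. The raw prediction can be negative
#' (the linear model knows nothing of the physical floor at zero); percent
#' errors are computed from the raw prediction, and a clipped `max(0, raw)`
#' column is reported alongside for display. A forecast year that appears in
#' the model's training years is refused (leakage guard).
#'
#' @param fit An [fit_ols()] result carrying its training `years`.
#' @param predictor data.frame `kelp_year, value` for the forecast years.
#' @param observed data.frame `year, extent_km2` (NA = missing) for the same
#'   region; may omit forecast years.
#' @return data.frame `year, x, predicted_km2, predicted_km2_clipped,
#'   observed_km2, error_pct` with `error_pct` NA where the observation is
#'   missing or zero.
#' @export
forecast_years <- function(fit, predictor, observed) {
  stopifnot(inherits(fit, "ols_fit"),
            all(c("kelp_year", "value") %in% names(predictor)))
  if (is.null(fit$years)) {
    stop("forecast_years: fit does not record its training years")
  }
  leak <- intersect(predictor$kelp_year, fit$years)
  if (length(leak) > 0) {
    stop("forecast_years: forecast year(s) ", paste(leak, collapse = ", "),
         " are in the model's training period")
  }
  pred <- predictor[is.finite(predictor$value), , drop = FALSE]
  pred <- pred[order(pred$kelp_year), , drop = FALSE]
  yhat <- predict(fit, pred$value)
  obs <- observed$extent_km2[match(pred$kelp_year, observed$year)]
  err <- ifelse(!is.na(obs) & obs != 0, abs(obs - yhat) / abs(obs) * 100,
                NA_real_)
  data.frame(
    year = pred$kelp_year, x = pred$value,
    predicted_km2 = yhat, predicted_km2_clipped = pmax(0, yhat),
    observed_km2 = obs, error_pct = err, row.names = NULL
  )
}
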