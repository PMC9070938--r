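# Leave-one-out cross-validation: refit precision and predictability error.

#' Leave-one-out cross-validation of a univariate kelp model
#'
#' For each complete-case year, the model is refit on all remaining years and
#' used to predict the held-out year. Two statistics are reported per year:
#' the refit's in-sample R-squared (their mean is the model's precision) and
#' the percent predictability error `|measured - predicted| / |measured| *
#' 100`. A year with a measured value of exactly 0 has an undefined percent
#' error: it is kept in the table with `error_pct = NA`, excluded from the
#' aggregates, and a warning is issued. Measured values are otherwise used
#' raw, however small, so single years can show triple-digit errors.
#'
#' @param pairs Complete-case pairs from [build_pairs()] (needs `kelp_year`,
#'   `x`, `y`; at least 4 rows so each refit keeps 3).
#' @return An object of class `loo_report`: list with `per_year` (data.frame
#'   `kelp_year, observed_km2, predicted_km2, error_pct, refit_r2`),
#'   `mean_refit_r_squared`, `mean_error_pct`, `sd_error_pct` and `n`.
#' @export
loo_cross_validate <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("kelp_year", "x", "y") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 4) stop("loo_cross_validate: need at least 4 pairs, got ", n)
  rows <- lapply(seq_len(n), function(i) {
    fit <- fit_ols(pairs[-i, , drop = FALSE])
    pred <- predict(fit, pairs$x[i])
    obs <- pairs$y[i]
    err <- if (obs == 0) NA_real_ else abs(obs - pred) / abs(obs) * 100
    data.frame(
      kelp_year = pairs$kelp_year[i], observed_km2 = obs,
      predicted_km2 = pred, error_pct = err, refit_r2 = fit$r_squared
    )
  })
  per_year <- do.call(rbind, rows)
  if (anyNA(per_year$error_pct)) {
    warning("leave-one-out: year(s) with measured extent 0 have undefined ",
            "percent error and are excluded from the aggregates: ",
            paste(per_year$kelp_year[is.na(per_year$error_pct)],
                  collapse = ", "))
  }
  err <- per_year$error_pct[!is.na(per_year$error_pct)]
  structure(list(
    per_year = per_year,
    mean_refit_r_squared = mean(per_year$refit_r2),
    mean_error_pct = mean(err),
    sd_error_pct = stats::sd(err),
    n = n
  ), class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out over %d years: precision (mean refit R2) = %.3f, ",
    x$n, x$mean_refit_r_squared
  ))
  cat(sprintf("predictability error = %.0f%% (sd %.0f%%)\n",
              x$mean_error_pct, x$sd_error_pct))
  invisible(x)
}
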