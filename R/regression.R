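# Univariate regression screening, AIC model selection, and the auxiliary
# correlation / trend statistics.
#
# Every candidate model is ordinary least squares of annual regional kelp
# extent (km2) on one seasonal predictor. Significance is the two-sided t-test
# on the slope (identical to the model F-test in the univariate case); model
# comparison uses a Gaussian maximum-likelihood AIC with a pinned convention
# so values are reproducible: AIC = n*log(2*pi*sse/n) + n + 2k, k = 2.

#' Gaussian maximum-likelihood AIC for a least-squares fit
#'
#' Convention: `n*log(2*pi*sse/n) + n + 2k` with `k = 2` mean parameters
#' (slope and intercept). Only differences between models fit to the same `n`
#' are meaningful. A perfect fit (`sse = 0`) returns `-Inf`.
#'
#' @param n Number of observations.
#' @param sse Residual sum of squares.
#' @param k Number of mean parameters. Default 2.
#' @return The AIC value (`-Inf` when `sse` is 0).
#' @export
ols_aic <- function(n, sse, k = 2) {
  stopifnot(n >= 1, sse >= 0)
  if (sse == 0) return(-Inf)
  n * log(2 * pi * sse / n) + n + 2 * k
}

#' Fit a univariate ordinary-least-squares model
#'
#' Fits `y = intercept + slope * x` by least squares (via [stats::lm()]) and
#' reports the quantities the screening and validation stages need. The
#' two-sided p-value for the slope uses the t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param pairs data.frame with columns `x`, `y` and (optionally) `kelp_year`;
#'   see [build_pairs()].
#' @return An object of class `ols_fit`: a list with `slope`, `intercept`,
#'   `n`, `r_squared`, `p_slope`, `se_slope`, `sse`, `aic` and `years` (the
#'   training years, NULL when `kelp_year` is absent).
#' @examples
#' fit_ols(data.frame(x = 0:3, y = 2 * (0:3) + 1))
#' @export
fit_ols <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  x <- pairs$x
  y <- pairs$y
  n <- length(x)
  if (n < 3) stop("fit_ols: need at least 3 complete pairs, got ", n)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("fit_ols: non-finite values in pairs")
  }
  if (max(x) == min(x)) stop("fit_ols: predictor is constant")
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  # an exact linear relationship leaves only rounding noise in the residuals;
  # snap it to zero so the perfect-fit AIC sentinel engages
  if (sse <= 1e-12 * sst) sse <- 0
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  # summary.lm warns on exact fits ("essentially perfect fit"); sse = 0 is a
  # legitimate case here (noiseless synthetic data), handled via the AIC
  # sentinel, so the warning is suppressed
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(
    slope = unname(coefs["x"]),
    intercept = unname(coefs["(Intercept)"]),
    n = n,
    r_squared = r2,
    p_slope = unname(sm["x", "Pr(>|t|)"]),
    se_slope = unname(sm["x", "Std. Error"]),
    sse = sse,
    aic = ols_aic(n, sse, k = 2),
    years = if ("kelp_year" %in% names(pairs)) pairs$kelp_year else NULL
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit: y = %.4g %+.4g * x  (n = %d, R2 = %.3f, p = %.3g, AIC = %.1f)\n",
    x$intercept, x$slope, x$n, x$r_squared, x$p_slope, x$aic
  ))
  invisible(x)
}

#' Predict from an `ols_fit`
#' @param object An [fit_ols()] result.
#' @param newx Numeric vector of predictor values.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ols_fit <- function(object, newx, ...) {
  object$intercept + object$slope * newx
}

#' Screen all (region, index, season) model candidates
#'
#' Fits one univariate model per combination of region, predictor index and
#' season, and masks cells whose slope p-value is not below `alpha`
#' (mirroring a screening table where only significant regressions are
#' shown). Combinations with fewer than 3 complete pairs or a constant
#' predictor are masked with NA statistics rather than failing.
#'
#' @param kelp data.frame `region, year, extent_km2` as returned by
#'   [aggregate_regional_series()].
#' @param predictors data.frame `index_name, season, kelp_year, value` as
#'   returned by [seasonal_predictors()].
#' @param alpha Significance level for the mask. Default 0.05.
#' @param year_range Optional restriction of the years used (e.g. the
#'   pre-collapse period).
#' @return data.frame `region, index_name, season, n, r_squared, p, aic,
#'   slope, intercept, masked`, one row per combination.
#' @export
screen_models <- function(kelp, predictors, alpha = 0.05, year_range = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  combos <- expand.grid(
    region = unique(kelp$region),
    index_name = unique(predictors$index_name),
    season = unique(predictors$season),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    reg <- combos$region[i]
    idx <- combos$index_name[i]
    se <- combos$season[i]
    pred <- predictors[predictors$index_name == idx &
                         predictors$season == se, , drop = FALSE]
    pairs <- build_pairs(kelp[kelp$region == reg, ], pred, year_range)
    base <- data.frame(
      region = reg, index_name = idx, season = se, n = nrow(pairs),
      r_squared = NA_real_, p = NA_real_, aic = NA_real_,
      slope = NA_real_, intercept = NA_real_, masked = TRUE,
      stringsAsFactors = FALSE
    )
    if (nrow(pairs) < 3 || max(pairs$x) == min(pairs$x)) return(base)
    fit <- fit_ols(pairs)
    base$r_squared <- fit$r_squared
    base$p <- fit$p_slope
    base$aic <- fit$aic
    base$slope <- fit$slope
    base$intercept <- fit$intercept
    base$masked <- !(fit$p_slope < alpha)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best model per region from a screening table
#'
#' Among unmasked (significant) candidates the winner has the lowest AIC;
#' ties are broken by higher R-squared, then lexicographically by index name
#' so selection is deterministic and invariant to row order.
#'
#' @param screen One region's rows of a [screen_models()] table.
#' @return The selected row (one-row data.frame), or `NULL` when no
#'   candidate is significant ("no model selected").
#' @export
select_model <- function(screen) {
  cand <- screen[!screen$masked & !is.na(screen$aic), , drop = FALSE]
  if (nrow(cand) == 0) {
    message("no model selected: no significant candidate")
    return(NULL)
  }
  ord <- order(cand$aic, -cand$r_squared, cand$index_name, cand$season)
  out <- cand[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-test p-value
#'
#' Product-moment correlation on complete cases, with the p-value from the t
#' distribution on `n - 2` degrees of freedom (via [stats::cor.test()]). Used
#' for the between-region covariability check and season-lag correlation
#' tables.
#'
#' @param x,y Numeric vectors of equal length; pairs with NA on either side
#'   are dropped.
#' @return List with `rho`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_correlation: need at least 3 complete pairs")
  if (max(x) == min(x) || max(y) == min(y)) {
    stop("pearson_correlation: constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Linear trend test for an annual series
#'
#' Regresses the values on calendar year and reports the slope (units per
#' year) and its two-sided p-value.
#'
#' @param years Integer vector of years.
#' @param values Numeric vector, NA allowed (dropped).
#' @return List with `slope`, `p`, `n` and the underlying `fit`.
#' @export
linear_trend_test <- function(years, values) {
  stopifnot(length(years) == length(values))
  ok <- is.finite(values)
  pairs <- data.frame(kelp_year = years[ok], x = years[ok], y = values[ok])
  fit <- fit_ols(pairs)
  list(slope = fit$slope, p = fit$p_slope, n = fit$n, fit = fit)
}
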