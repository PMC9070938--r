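#!/usr/bin/env Rscript
# Stage 3: seasonal predictors, regression screen and model selection.
#
# Averages each monthly index over fall (previous year), winter, spring and
# summer; regresses pre-collapse (1991-2013) regional kelp extent on every
# (index, season) candidate; masks cells with p >= 0.05; and selects the
# lowest-AIC significant model per region.
#
# Reads:  results/regional_series.csv, results/monthly_indices.csv
# Writes: results/seasonal_predictors.csv, results/screen_table.csv,
#         results/model_table.csv

library(nereocast)

series <- read.csv("results/regional_series.csv")
indices <- read_index_csv("results/monthly_indices.csv")
pre_years <- 1991:2013

predictors <- seasonal_predictors(indices, 1991:2020)
write.csv(predictors, "results/seasonal_predictors.csv", row.names = FALSE,
          na = "")

screen <- screen_models(series, predictors, alpha = 0.05,
                        year_range = pre_years)
write.csv(screen, "results/screen_table.csv", row.names = FALSE, na = "")

models <- NULL
for (reg in unique(series$region)) {
  sel <- select_model(screen[screen$region == reg, ])
  if (is.null(sel)) {
    cat(reg, ": no significant candidate at alpha = 0.05\n")
    next
  }
  cat(sprintf("%s: best model %s %s  (R2 = %.2f, p = %.2g, AIC = %.1f, n = %d)\n",
              reg, sel$season, sel$index_name, sel$r_squared, sel$p, sel$aic,
              sel$n))
  models <- rbind(models, sel)
}
if (!is.null(models)) {
  write.csv(models, "results/model_table.csv", row.names = FALSE)
}

win <- screen[screen$season == "winter" & !screen$masked, ]
cat(sprintf("screen: %d/%d cells significant; winter cells span R2 %.2f-%.2f\n",
            sum(!screen$masked), nrow(screen),
            min(win$r_squared), max(win$r_squared)))
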