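#' Fit a linear yield trend
#'
#' Ordinary least squares of yield on year. The relative trend
#' (percent per year) uses the fitted value at the series' first year as
#' its base by default; `base = "mean"` uses the mean fitted value instead.
#'
#' @param series Data.frame with columns `year` and `yield_t_ha` (>= 3
#'   rows).
#' @param base Base for the percentage trend: `"first"` (fitted value at
#'   the first year) or `"mean"`.
#' @return List with `slope` (t/ha/yr), `pct_per_year` (%/yr), `p_value`,
#'   and the `fit` (an `lm`).
#' @export
fit_yield_trend <- function(series, base = c("first", "mean")) {
  base <- match.arg(base)
  if (nrow(series) < 3) stop("at least 3 years are required to fit a trend")
  fit <- stats::lm(yield_t_ha ~ year, data = series)
  slope <- unname(stats::coef(fit)["year"])
  denom <- if (base == "first") {
    unname(stats::predict(fit, data.frame(year = min(series$year))))
  } else {
    mean(stats::fitted(fit))
  }
  # a perfect (zero-residual) fit is legitimate input; silence summary.lm
  p <- suppressWarnings(summary(fit))$coefficients["year", "Pr(>|t|)"]
  list(slope = slope,
       pct_per_year = if (denom > 0) 100 * slope / denom else NA_real_,
       p_value = unname(p), fit = fit)
}

#' Yield gap
#'
#' `100 * (water_limited - observed) / water_limited` percent. A negative
#' gap (observed above the simulated water-limited yield) is returned with
#' an `out_of_range` attribute set.
#'
#' @param water_limited Simulated water-limited yield (t/ha, > 0).
#' @param observed Observed yield (t/ha, >= 0).
#' @return Gap in percent (possibly negative).
#' @export
yield_gap <- function(water_limited, observed) {
  if (any(water_limited <= 0)) stop("water_limited must be > 0")
  if (any(observed < 0)) stop("observed must be >= 0")
  gap <- 100 * (water_limited - observed) / water_limited
  attr(gap, "out_of_range") <- gap < 0
  gap
}

#' Convert traded soybean products to seed equivalents
#'
#' Whole-bean mass equivalent of seed, oil and cake trade flows:
#' `seed + oil / oil_to_seed + cake / cake_to_seed`.
#'
#' @param seed,oil,cake Trade masses (same unit, >= 0).
#' @param oil_to_seed,cake_to_seed Extraction ratios in (0, 1).
#' @return Seed-equivalent mass.
#' @export
seed_equivalents <- function(seed, oil, cake,
                             oil_to_seed = 0.178, cake_to_seed = 0.792) {
  if (any(c(seed, oil, cake) < 0)) stop("trade masses must be >= 0")
  stopifnot(oil_to_seed > 0, oil_to_seed < 1, cake_to_seed > 0,
            cake_to_seed < 1)
  seed + oil / oil_to_seed + cake / cake_to_seed
}

#' Model-validation metrics
#'
#' Pearson correlation, mean bias error (mean of simulated minus observed;
#' negative = underestimation) and mean absolute percentage error between
#' simulated and observed yields. With a constant vector the correlation is
#' undefined and reported as `NA`; the other metrics are still returned.
#'
#' @param simulated,observed Equal-length numeric vectors (length >= 2);
#'   `observed` must be positive for the MAPE.
#' @return List with `pearson_r`, `mbe`, `mape` (percent).
#' @export
validation_metrics <- function(simulated, observed) {
  stopifnot(length(simulated) == length(observed), length(simulated) >= 2)
  if (any(observed <= 0)) stop("observed values must be > 0 for the MAPE")
  r <- if (stats::sd(simulated) == 0 || stats::sd(observed) == 0)
    NA_real_ else stats::cor(simulated, observed)
  list(pearson_r = r,
       mbe = mean(simulated - observed),
       mape = 100 * mean(abs(simulated - observed) / observed))
}
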