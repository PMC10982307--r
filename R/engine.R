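#' Failure rules for a simulated season
#'
#' A season fails if planting never occurred, if the daily mean temperature
#' drops below the frost threshold on any day between emergence and
#' physiological maturity, or if the planting-to-maturity cycle exceeds the
#' maximum duration (strictly greater than `max_cycle_days`). Failed seasons
#' yield 0; successful yields are capped at `cap_yield`.
#'
#' @param frost_threshold Daily mean temperature (degC) below which the crop
#'   is killed (default 0).
#' @param max_cycle_days Maximum allowed days from planting to R7
#'   (default 170).
#' @param cap_yield Maximum plausible attainable yield (t/ha, default 7).
#' @return An object of class `failure_rules`.
#' @export
failure_rules <- function(frost_threshold = 0, max_cycle_days = 170,
                          cap_yield = 7) {
  assert_scalar(max_cycle_days, "max_cycle_days", 0, Inf, strict_lower = TRUE)
  assert_scalar(cap_yield, "cap_yield", 0, Inf, strict_lower = TRUE)
  structure(list(frost_threshold = frost_threshold,
                 max_cycle_days = max_cycle_days, cap_yield = cap_yield),
            class = "failure_rules")
}

#' Classify a site-season against the failure rules
#'
#' Precedence: `no_planting` first; then `frost` (daily mean below the
#' threshold between emergence and R7, or between emergence and the end of
#' the series when maturity was never reached); then `overlong` (cycle
#' longer than the limit, or maturity never reached). Returns `"none"` for a
#' successful season.
#'
#' @param series Single-year daily weather data.frame.
#' @param stages A `stage_dates` (with `planting` possibly `NA`).
#' @param rules A [failure_rules].
#' @return One of `"no_planting"`, `"frost"`, `"overlong"`, `"none"`.
#' @export
apply_failure_rules <- function(series, stages, rules = failure_rules()) {
  if (is.na(stages$planting)) return("no_planting")
  series <- series_one_year(series)
  if (!is.na(stages$emergence)) {
    hi <- if (stages$reached_r7) stages$r7 else max(series$doy)
    win <- series$doy >= stages$emergence & series$doy <= hi
    tmean <- (series$tmin_c[win] + series$tmax_c[win]) / 2
    if (any(tmean < rules$frost_threshold)) return("frost")
  }
  if (!stages$reached_r7) return("overlong")
  if (stages$r7 - stages$planting > rules$max_cycle_days) return("overlong")
  "none"
}

#' Cap a raw yield at the plausible maximum
#'
#' @param raw Raw simulated yield (t/ha, >= 0).
#' @param rules A [failure_rules].
#' @return `min(raw, cap_yield)`.
#' @export
cap_yield <- function(raw, rules = failure_rules()) {
  if (any(raw < 0)) stop("raw yield must be >= 0")
  pmin(raw, rules$cap_yield)
}

#' Run the full site x year x maturity group x configuration factorial
#'
#' Orchestrates the phenology and growth models over every combination:
#' planting is decided once per site-year (shared across maturity groups and
#' configurations), stages per maturity group, failure rules applied, and a
#' season simulated per configuration. Failed seasons are recorded with
#' yield 0 and their failure reason; successful yields are capped. The
#' result count is exactly the Cartesian product size, and re-running with
#' identical inputs is bit-identical (all stochasticity lives in the
#' synthetic-input seeds).
#'
#' @param grid Site data.frame (`site_id`, `lat`, `lon`) from
#'   [gen_site_grid].
#' @param weather Named list (by `site_id`) of multi-year daily weather
#'   data.frames.
#' @param soils Named list (by `site_id`) of `list(soil, moisture)` as from
#'   [gen_soil].
#' @param mgs Maturity-group labels (default all seven).
#' @param configs List of [sim_configuration]s (default the four study
#'   configurations).
#' @param rules A [failure_rules].
#' @param phen_cfg A [phenology_config].
#' @param growth_cfg A [growth_config].
#' @return A long-format data.frame, one row per simulation, with columns
#'   `site_id`, `year`, `mg`, `config`, `planting_doy`, `emergence_doy`,
#'   `r1_doy`, `r5_doy`, `r7_doy`, `yield_t_ha`, `failed`, `failure_reason`.
#' @export
run_factorial <- function(grid, weather, soils,
                          mgs = default_mg_targets()$mg,
                          configs = default_configurations(),
                          rules = failure_rules(),
                          phen_cfg = phenology_config(),
                          growth_cfg = growth_config()) {
  missing_w <- setdiff(grid$site_id, names(weather))
  missing_s <- setdiff(grid$site_id, names(soils))
  if (length(missing_w) || length(missing_s))
    stop("missing input data for sites: ",
         paste(unique(c(missing_w, missing_s)), collapse = ", "))

  rows <- vector("list", 0L)
  for (si in seq_len(nrow(grid))) {
    sid <- grid$site_id[si]
    series_all <- weather[[sid]]
    lat <- attr(series_all, "lat")
    if (is.null(lat)) lat <- grid$lat[si]
    sl <- soils[[sid]]
    for (yr in sort(unique(series_all$year))) {
      sy <- series_all[series_all$year == yr, , drop = FALSE]
      attr(sy, "lat") <- lat
      planting <- decide_planting(sy, phen_cfg)
      for (mg in mgs) {
        if (is.na(planting)) {
          stages <- structure(list(planting = NA_integer_,
                                   emergence = NA_integer_, r1 = NA_integer_,
                                   r5 = NA_integer_, r7 = NA_integer_,
                                   reached_r7 = FALSE), class = "stage_dates")
        } else {
          stages <- predict_stages(sy, planting, mg, phen_cfg, lat = lat)
        }
        reason <- apply_failure_rules(sy, stages, rules)
        for (cf in configs) {
          yld <- 0
          if (reason == "none") {
            sim <- simulate_season(sy, stages, sl$soil, sl$moisture, cf,
                                   growth_cfg)
            yld <- cap_yield(sim$yield_t_ha, rules)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = sid, year = yr, mg = mg, config = cf$label,
            planting_doy = stages$planting, emergence_doy = stages$emergence,
            r1_doy = stages$r1, r5_doy = stages$r5, r7_doy = stages$r7,
            yield_t_ha = yld, failed = reason != "none",
            failure_reason = reason, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size of the factorial design
#'
#' Count arithmetic on the declared design without executing it: sites x
#' years x maturity groups x configurations.
#'
#' @param n_sites,n_years,n_mgs,n_configs Design dimensions.
#' @return Total number of simulations.
#' @export
factorial_size <- function(n_sites, n_years, n_mgs = 7, n_configs = 4) {
  as.numeric(n_sites) * n_years * n_mgs * n_configs
}
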