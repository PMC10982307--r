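#' Climate archetype
#'
#' A parametric monthly climatology from which the synthetic weather
#' generator draws daily series: mean monthly minimum/maximum temperature,
#' mean monthly precipitation totals, a wet-day probability, the annual peak
#' of daily solar radiation, and the between-year temperature variability.
#'
#' @param name Label for the archetype.
#' @param monthly_tmin_mean,monthly_tmax_mean Numeric length-12, mean daily
#'   minimum / maximum temperature per calendar month (degC).
#' @param monthly_precip_mean Numeric length-12, mean precipitation total per
#'   calendar month (mm).
#' @param precip_wet_day_prob Probability that any day is wet, in `[0, 1]`.
#' @param srad_annual_peak Midsummer peak of daily solar radiation
#'   (MJ m-2 d-1).
#' @param interannual_sd Standard deviation of the yearly temperature offset
#'   (degC).
#' @return An object of class `climate_archetype`.
#' @export
climate_archetype <- function(name, monthly_tmin_mean, monthly_tmax_mean,
                              monthly_precip_mean, precip_wet_day_prob,
                              srad_annual_peak, interannual_sd) {
  stopifnot(is.character(name), length(name) == 1L,
            length(monthly_tmin_mean) == 12L,
            length(monthly_tmax_mean) == 12L,
            length(monthly_precip_mean) == 12L)
  if (any(monthly_tmax_mean <= monthly_tmin_mean))
    stop("monthly_tmax_mean must exceed monthly_tmin_mean in every month")
  if (any(monthly_tmax_mean - monthly_tmin_mean > 25))
    stop("monthly diurnal range must not exceed 25 degC")
  if (any(monthly_precip_mean < 0))
    stop("monthly_precip_mean must be non-negative")
  assert_scalar(precip_wet_day_prob, "precip_wet_day_prob", 0, 1)
  assert_scalar(srad_annual_peak, "srad_annual_peak", 0, Inf, strict_lower = TRUE)
  assert_scalar(interannual_sd, "interannual_sd", 0, Inf)
  structure(list(name = name,
                 monthly_tmin_mean = as.numeric(monthly_tmin_mean),
                 monthly_tmax_mean = as.numeric(monthly_tmax_mean),
                 monthly_precip_mean = as.numeric(monthly_precip_mean),
                 precip_wet_day_prob = precip_wet_day_prob,
                 srad_annual_peak = srad_annual_peak,
                 interannual_sd = interannual_sd),
            class = "climate_archetype")
}

#' Read a climate-archetype registry from YAML
#'
#' Each top-level key names an archetype whose fields match the
#' [climate_archetype] constructor; every entry is validated on load.
#'
#' @param path YAML file; defaults to the packaged registry, which mirrors
#'   [default_archetypes].
#' @return Named list of [climate_archetype] objects.
#' @export
read_archetypes <- function(path = system.file("extdata", "archetypes.yaml",
                                               package = "eurosoy")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    a <- raw[[nm]]
    climate_archetype(nm, a$monthly_tmin_mean, a$monthly_tmax_mean,
                      a$monthly_precip_mean, a$precip_wet_day_prob,
                      a$srad_annual_peak, a$interannual_sd)
  })
  stats::setNames(out, names(raw))
}

#' Default climate archetypes
#'
#' Four synthetic European climate archetypes used by the site-grid
#' simulations: temperate maritime (western Europe), continental (central to
#' eastern Europe), Mediterranean (southern Europe) and sub-arctic (northern
#' margins). Parameters are stylised climatologies chosen so the crop engine
#' reproduces the qualitative pattern of regional outcomes (warm-season
#' thermal time ordered Mediterranean > continental > maritime > sub-arctic;
#' no completed cycle in the sub-arctic); they are synthetic, not calibrated
#' to any observational record.
#'
#' @param lat Reference latitude (degrees) only recorded as an attribute for
#'   convenience; generators take latitude explicitly.
#' @return Named list of [climate_archetype] objects.
#' @export
default_archetypes <- function(lat = NULL) {
  list(
    maritime = climate_archetype(
      "maritime",
      monthly_tmin_mean = c(2, 2, 4, 6, 9, 12, 14, 14, 12, 9, 5, 3),
      monthly_tmax_mean = c(8, 9, 12, 16, 19, 22, 24, 24, 21, 16, 11, 9),
      monthly_precip_mean = c(70, 55, 55, 50, 55, 55, 60, 65, 60, 75, 75, 75),
      precip_wet_day_prob = 0.45,
      srad_annual_peak = 20,
      interannual_sd = 0.8),
    continental = climate_archetype(
      "continental",
      monthly_tmin_mean = c(-6, -5, -1, 4, 9, 13, 16, 15, 10, 4, 0, -4),
      monthly_tmax_mean = c(0, 2, 8, 15, 21, 26, 28, 27, 21, 13, 6, 1),
      monthly_precip_mean = c(35, 30, 35, 40, 55, 70, 75, 65, 45, 40, 40, 40),
      precip_wet_day_prob = 0.35,
      srad_annual_peak = 23,
      interannual_sd = 1.2),
    mediterranean = climate_archetype(
      "mediterranean",
      monthly_tmin_mean = c(3, 3, 5, 8, 12, 16, 18, 18, 15, 11, 7, 4),
      monthly_tmax_mean = c(11, 12, 15, 18, 23, 28, 31, 31, 26, 20, 15, 12),
      monthly_precip_mean = c(55, 45, 45, 45, 35, 20, 10, 15, 40, 65, 70, 60),
      precip_wet_day_prob = 0.28,
      srad_annual_peak = 26,
      interannual_sd = 1.0),
    subarctic = climate_archetype(
      "subarctic",
      monthly_tmin_mean = c(-14, -13, -9, -3, 2, 7, 9, 8, 4, -1, -7, -12),
      monthly_tmax_mean = c(-7, -6, -1, 4, 9, 13, 14.5, 13, 8, 2, -3, -6),
      monthly_precip_mean = c(30, 25, 25, 30, 40, 50, 60, 55, 50, 45, 40, 35),
      precip_wet_day_prob = 0.40,
      srad_annual_peak = 20,
      interannual_sd = 1.5)
  )
}
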