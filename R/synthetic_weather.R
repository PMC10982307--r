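# First annual Fourier harmonic through 12 monthly values placed at month
# midpoints; returns a function of day-of-year. This is the "sinusoidal
# interpolation" of the monthly climatology.
harmonic_fit <- function(monthly) {
  mid <- c(15.5, 45, 74.5, 105, 135.5, 166, 196.5, 227.5, 258, 288.5, 319, 349.5)
  w <- 2 * pi * mid / 365.25
  X <- cbind(1, cos(w), sin(w))
  beta <- solve(crossprod(X), crossprod(X, monthly))
  function(doy) {
    wd <- 2 * pi * doy / 365.25
    as.numeric(beta[1] + beta[2] * cos(wd) + beta[3] * sin(wd))
  }
}

#' Generate a synthetic daily weather series
#'
#' Draws a multi-year daily series (tmin, tmax, precipitation, solar
#' radiation) from a [climate_archetype]. Temperature is the sinusoidally
#' interpolated monthly climatology plus a yearly offset and an AR(1) daily
#' anomaly shared by tmin and tmax; the diurnal range follows the
#' climatology, bounded to (0, 24] degC. Precipitation is Bernoulli-gamma:
#' each day is wet with the archetype's wet-day probability and wet-day
#' amounts are gamma-distributed with monthly means that reproduce the
#' climatological monthly totals in expectation. Solar radiation follows an
#' annual sinusoid peaking at the summer solstice with mild lognormal noise
#' and dimming on wet days.
#'
#' Calendar dates follow the proleptic Gregorian calendar (leap years
#' included); downstream stage arithmetic uses day-of-year.
#'
#' @param archetype A [climate_archetype].
#' @param n_years Number of calendar years to generate (>= 1).
#' @param seed Integer seed; identical arguments give identical series.
#' @param start_year First calendar year (default 1999).
#' @param site_id Site identifier stored in the series.
#' @param lat Site latitude in degrees, stored as attribute `lat` and used
#'   downstream for daylength.
#' @return A data.frame with columns `site_id`, `date`, `year`, `doy`,
#'   `tmin_c`, `tmax_c`, `precip_mm`, `srad_mj_m2`, one row per calendar day.
#' @export
gen_weather <- function(archetype, n_years, seed, start_year = 1999,
                        site_id = "S1", lat = 50) {
  stopifnot(inherits(archetype, "climate_archetype"))
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years < 1)
    stop("n_years must be a positive count")
  n_years <- as.integer(n_years)

  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
               by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  year <- as.integer(strftime(dates, "%Y"))
  month <- as.integer(strftime(dates, "%m"))
  n <- length(dates)

  f_tmin <- harmonic_fit(archetype$monthly_tmin_mean)
  f_range <- harmonic_fit(archetype$monthly_tmax_mean - archetype$monthly_tmin_mean)
  clim_tmin <- f_tmin(doy)
  clim_range <- pmin(24, pmax(0.5, f_range(doy)))

  with_seed(seed, {
    # yearly offset + AR(1) daily anomaly, shared by tmin and tmax
    yr_off <- stats::rnorm(n_years, 0, archetype$interannual_sd)[year - start_year + 1L]
    rho <- 0.7
    anom_sd <- 1.8
    innov <- stats::rnorm(n, 0, anom_sd * sqrt(1 - rho^2))
    z <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    z[1] <- stats::rnorm(1, 0, anom_sd)
    tmin <- clim_tmin + yr_off + z
    tmax <- tmin + clim_range

    p_wet <- archetype$precip_wet_day_prob
    precip <- numeric(n)
    if (p_wet > 0) {
      wet <- stats::runif(n) < p_wet
      days_in_month <- tabulate(month[year == year[1]], 12)
      mean_wet <- archetype$monthly_precip_mean[month] /
        pmax(1, days_in_month[month] * p_wet)
      shape <- 0.75
      amounts <- stats::rgamma(n, shape = shape, scale = pmax(mean_wet, 1e-9) / shape)
      precip[wet] <- amounts[wet]
    } else {
      wet <- rep(FALSE, n)
    }

    season <- (1 + cos(2 * pi * (doy - 172) / 365.25)) / 2
    srad <- archetype$srad_annual_peak * (0.22 + 0.78 * season)
    srad <- srad * exp(stats::rnorm(n, 0, 0.08)) * ifelse(wet, 0.8, 1)

    out <- data.frame(site_id = site_id, date = dates, year = year, doy = doy,
                      tmin_c = tmin, tmax_c = tmax, precip_mm = precip,
                      srad_mj_m2 = srad, stringsAsFactors = FALSE)
    attr(out, "lat") <- lat
    out
  })
}

#' Generate a synthetic soil profile and initial-moisture estimate
#'
#' Draws plausible root-zone soil properties (porosity, wilting point,
#' plant-available water capacity over a 1 m root zone) and a satellite-style
#' root-zone moisture estimate (ensemble mean and standard deviation) lying
#' between wilting point and porosity.
#'
#' @param seed Integer seed.
#' @return List with elements `soil` (class `soil_profile`: `paw_capacity`
#'   mm, `wilting_point`, `porosity`, `rootzone_depth` m) and `moisture`
#'   (class `moisture_init`: `sm_mean`, `sm_ensemble_sd`, volumetric
#'   fractions).
#' @export
gen_soil <- function(seed) {
  with_seed(seed, {
    porosity <- stats::runif(1, 0.40, 0.55)
    wilting_point <- stats::runif(1, 0.08, 0.18)
    rootzone_depth <- 1.0
    # field capacity a fixed fraction of the wp-porosity span
    field_capacity <- wilting_point + 0.55 * (porosity - wilting_point)
    paw_capacity <- (field_capacity - wilting_point) * rootzone_depth * 1000
    frac <- stats::rbeta(1, 4, 2) # initial moisture position in [wp, porosity]
    sm_mean <- wilting_point + frac * (porosity - wilting_point)
    sm_ensemble_sd <- stats::runif(1, 0.01, 0.04)
    soil <- structure(list(paw_capacity = paw_capacity,
                           wilting_point = wilting_point,
                           porosity = porosity,
                           rootzone_depth = rootzone_depth),
                      class = "soil_profile")
    validate_soil(soil)
    moisture <- structure(list(sm_mean = sm_mean,
                               sm_ensemble_sd = sm_ensemble_sd),
                          class = "moisture_init")
    list(soil = soil, moisture = moisture)
  })
}

validate_soil <- function(soil) {
  with(soil, {
    if (!(wilting_point > 0 && wilting_point < porosity && porosity < 1))
      stop("soil invariant violated: need 0 < wilting_point < porosity < 1")
    if (paw_capacity <= 0) stop("paw_capacity must be positive")
    if (rootzone_depth <= 0) stop("rootzone_depth must be positive")
  })
  invisible(soil)
}

#' Generate a rectangular site grid
#'
#' Regular latitude-longitude grid of site centroids inside the study
#' bounding box, row-major site ids, spacing equal to `resolution`.
#'
#' @param n_lat,n_lon Number of grid rows (latitude) and columns (longitude),
#'   both >= 1.
#' @param resolution Grid spacing in degrees (default 0.5).
#' @param origin Latitude/longitude of the south-west corner; defaults to the
#'   study bounding box origin (35.8 N, -10.5 E).
#' @return A data.frame with columns `site_id`, `lat`, `lon`.
#' @export
gen_site_grid <- function(n_lat, n_lon, resolution = 0.5,
                          origin = c(lat = 35.8, lon = -10.5)) {
  if (n_lat < 1 || n_lon < 1) stop("grid dimensions must be >= 1")
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  lat <- origin[["lat"]] + resolution * (seq_len(n_lat) - 1L)
  lon <- origin[["lon"]] + resolution * (seq_len(n_lon) - 1L)
  g <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)[, c("lat", "lon")]
  g <- data.frame(site_id = sprintf("S%04d", seq_len(nrow(g))), g,
                  row.names = NULL, stringsAsFactors = FALSE)
  attr(g, "resolution") <- resolution
  g
}

#' Generate a linear-trend-plus-noise national yield series
#'
#' Emulates a national statistics yield time series: a linear trend in time
#' with Gaussian noise, floored at zero.
#'
#' @param start_year First year.
#' @param n_years Number of years (>= 3, so a trend is fittable).
#' @param intercept Yield at `start_year` (t/ha, > 0).
#' @param slope Trend (t/ha per year).
#' @param noise_sd Gaussian noise standard deviation (t/ha).
#' @param seed Integer seed.
#' @param country Label attached to the series.
#' @return A data.frame with columns `country`, `year`, `yield_t_ha`.
#' @export
gen_yield_series <- function(start_year, n_years, intercept, slope, noise_sd,
                             seed, country = "synthetic") {
  if (n_years < 3) stop("n_years must be >= 3 (trend unfittable otherwise)")
  assert_scalar(intercept, "intercept", 0, Inf, strict_lower = TRUE)
  assert_scalar(noise_sd, "noise_sd", 0, Inf)
  years <- start_year + seq_len(n_years) - 1L
  with_seed(seed, {
    y <- intercept + slope * (years - start_year) +
      stats::rnorm(n_years, 0, noise_sd)
    data.frame(country = country, year = years,
               yield_t_ha = pmax(0, y), stringsAsFactors = FALSE)
  })
}
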