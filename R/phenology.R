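#' Phenology configuration
#'
#' Parameters of the thermal-time phenology model: the growing-degree-unit
#' (GDU) base and ceiling temperatures, the adaptive planting rule (trailing
#' 7-day mean GDU must exceed a threshold, no earlier than 1 March and no
#' later than 30 June), thermal time to emergence, per-maturity-group
#' cumulative GDU targets from emergence to flowering (R1), start of seed
#' fill (R5) and physiological maturity (R7), and a photoperiod modifier
#' that slows development in daylengths beyond a critical value.
#'
#' Maturity groups run 0000 (earliest) to III (latest); R7 targets increase
#' strictly with later groups. The development-rate modifier is
#' `1 - sens * max(0, daylength - critical)`, applied multiplicatively to
#' daily GDU between emergence and maturity.
#'
#' @param gdu_base,gdu_max GDU base and ceiling temperatures (degC).
#' @param planting_window Trailing window length in days.
#' @param planting_threshold GDU/day the window mean must exceed.
#' @param earliest_planting,latest_planting Calendar bounds as "MM-DD".
#' @param emergence_gdu Cumulative GDU from planting to emergence.
#' @param mg_targets Data frame with columns `mg`, `r1`, `r5`, `r7`
#'   (cumulative GDU from emergence) and `photoperiod_sens` (h-1).
#' @param photoperiod_critical Critical daylength (h).
#' @return An object of class `phenology_config`.
#' @export
phenology_config <- function(gdu_base = 10, gdu_max = 30,
                             planting_window = 7, planting_threshold = 4.4,
                             earliest_planting = "03-01",
                             latest_planting = "06-30",
                             emergence_gdu = 70,
                             mg_targets = default_mg_targets(),
                             photoperiod_critical = 13.5) {
  if (gdu_base >= gdu_max) stop("gdu_base must be below gdu_max")
  assert_scalar(planting_threshold, "planting_threshold", 0, Inf, strict_lower = TRUE)
  assert_scalar(emergence_gdu, "emergence_gdu", 0, Inf, strict_lower = TRUE)
  stopifnot(is.data.frame(mg_targets),
            all(c("mg", "r1", "r5", "r7", "photoperiod_sens") %in% names(mg_targets)))
  if (any(!(mg_targets$r1 < mg_targets$r5 & mg_targets$r5 < mg_targets$r7)))
    stop("per-MG targets must satisfy r1 < r5 < r7")
  if (any(diff(mg_targets$r7) <= 0))
    stop("r7 targets must increase strictly with later maturity groups")
  structure(list(gdu_base = gdu_base, gdu_max = gdu_max,
                 planting_window = planting_window,
                 planting_threshold = planting_threshold,
                 earliest_planting = earliest_planting,
                 latest_planting = latest_planting,
                 emergence_gdu = emergence_gdu,
                 mg_targets = mg_targets,
                 photoperiod_critical = photoperiod_critical),
            class = "phenology_config")
}

#' Default maturity-group thermal targets
#'
#' Cumulative GDU from emergence to R1/R5/R7 for maturity groups 0000..III,
#' with photoperiod sensitivity increasing toward later groups. These are
#' editable model coefficients, not measurements.
#'
#' @return Data frame with one row per maturity group, earliest first.
#' @export
default_mg_targets <- function() {
  i <- 0:6
  data.frame(mg = c("0000", "000", "00", "0", "I", "II", "III"),
             r1 = 280 + 35 * i,
             r5 = 500 + 60 * i,
             r7 = 750 + 90 * i,
             photoperiod_sens = 0.02 + 0.005 * i,
             stringsAsFactors = FALSE)
}

#' Daily growing degree units
#'
#' GDU for one day: both cardinal temperatures are clamped to the
#' `[gdu_base, gdu_max]` range before averaging, then the base is
#' subtracted, so the result lies in `[0, gdu_max - gdu_base]`.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC); vectors
#'   allowed, `tmax >= tmin` required elementwise.
#' @param cfg A [phenology_config].
#' @return GDU per day, same length as the inputs.
#' @export
daily_gdu <- function(tmin, tmax, cfg = phenology_config()) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  lo <- cfg$gdu_base; hi <- cfg$gdu_max
  pmax(0, (pmin(pmax(tmax, lo), hi) + pmin(pmax(tmin, lo), hi)) / 2 - lo)
}

#' Civil daylength from latitude and day-of-year
#'
#' Standard solar-declination formula with the sun's centre at the horizon.
#'
#' @param lat Latitude in degrees.
#' @param doy Day of year (vector allowed).
#' @return Daylength in hours.
#' @export
daylength <- function(lat, doy) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25) * pi / 180
  latr <- lat * pi / 180
  cos_h <- pmin(1, pmax(-1, -tan(latr) * tan(decl)))
  24 / pi * acos(cos_h)
}

series_one_year <- function(series) {
  if (length(unique(series$year)) != 1L)
    stop("a single-year weather slice is required")
  series[order(series$doy), , drop = FALSE]
}

#' Adaptive planting date
#'
#' Returns the first day of year, no earlier than the earliest-planting date
#' and no later than the latest-planting cutoff, on which the trailing
#' `planting_window`-day mean GDU strictly exceeds the planting threshold;
#' `NA` if no such day exists (no planting that year). The trailing window
#' is causal: the first evaluable day is the window-th day of the series.
#'
#' @param series A single-year daily weather data.frame (as from
#'   [gen_weather]).
#' @param cfg A [phenology_config].
#' @return Planting day-of-year, or `NA_integer_`.
#' @export
decide_planting <- function(series, cfg = phenology_config()) {
  series <- series_one_year(series)
  w <- cfg$planting_window
  if (nrow(series) < w) stop("series shorter than the rolling window")
  gdu <- daily_gdu(series$tmin_c, series$tmax_c, cfg)
  roll <- as.numeric(stats::filter(gdu, rep(1 / w, w), sides = 1))
  yr <- series$year[1]
  earliest <- as.integer(strftime(as.Date(sprintf("%d-%s", yr, cfg$earliest_planting)), "%j"))
  latest <- as.integer(strftime(as.Date(sprintf("%d-%s", yr, cfg$latest_planting)), "%j"))
  ok <- !is.na(roll) & roll > cfg$planting_threshold &
    series$doy >= earliest & series$doy <= latest
  if (!any(ok)) return(NA_integer_)
  series$doy[which(ok)[1]]
}

#' Predict phenological stage dates
#'
#' Thermal-time stage prediction for one site-year and maturity group:
#' emergence on the first day the cumulative post-planting GDU reaches the
#' emergence requirement; R1, R5 and R7 on the first days the cumulative
#' photoperiod-modified GDU from emergence reaches the maturity group's
#' targets. Development rate is multiplied by
#' `max(0, 1 - sens * max(0, daylength - critical))` each day.
#'
#' @param series Single-year daily weather data.frame.
#' @param planting Planting day-of-year (from [decide_planting]).
#' @param mg Maturity group label present in `cfg$mg_targets$mg`.
#' @param cfg A [phenology_config].
#' @param lat Latitude in degrees; defaults to the series' `lat` attribute.
#' @return A list of class `stage_dates`: `planting`, `emergence`, `r1`,
#'   `r5`, `r7` (day-of-year or `NA`) and `reached_r7`.
#' @export
predict_stages <- function(series, planting, mg, cfg = phenology_config(),
                           lat = attr(series, "lat")) {
  series <- series_one_year(series)
  if (is.null(lat)) lat <- 50
  if (is.na(planting) || !planting %in% series$doy)
    stop("planting day must lie within the series")
  tgt <- cfg$mg_targets[cfg$mg_targets$mg == mg, ]
  if (nrow(tgt) != 1L) stop("unknown maturity group: ", mg)

  gdu <- daily_gdu(series$tmin_c, series$tmax_c, cfg)
  doy <- series$doy
  post <- doy > planting
  stage <- list(planting = as.integer(planting), emergence = NA_integer_,
                r1 = NA_integer_, r5 = NA_integer_, r7 = NA_integer_,
                reached_r7 = FALSE)

  cum <- cumsum(gdu[post])
  hit <- which(cum >= cfg$emergence_gdu)
  if (length(hit) == 0L) return(structure(stage, class = "stage_dates"))
  stage$emergence <- doy[post][hit[1]]

  dev <- doy > stage$emergence
  mod <- pmax(0, 1 - tgt$photoperiod_sens *
                pmax(0, daylength(lat, doy[dev]) - cfg$photoperiod_critical))
  cum_dev <- cumsum(gdu[dev] * mod)
  first_at <- function(target) {
    k <- which(cum_dev >= target)
    if (length(k) == 0L) NA_integer_ else doy[dev][k[1]]
  }
  stage$r1 <- first_at(tgt$r1)
  stage$r5 <- first_at(tgt$r5)
  stage$r7 <- first_at(tgt$r7)
  stage$reached_r7 <- !is.na(stage$r7)
  structure(stage, class = "stage_dates")
}
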