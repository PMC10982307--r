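#' Crop growth configuration
#'
#' Coefficients of the daily radiation-use-efficiency growth model:
#' expolinear leaf-area expansion, Beer-law light interception,
#' Priestley-Taylor evapotranspiration demand and a linear soil-water stress
#' response. Defaults are tuned so that the continental archetype produces
#' potential yields in the 3-5 t/ha range; they are model defaults, not
#' measurements.
#'
#' @param rue Radiation-use efficiency (g dry mass per MJ intercepted).
#' @param k_ext Canopy extinction coefficient (dimensionless).
#' @param c_l Expolinear linear-phase LAI growth rate (LAI/day).
#' @param r_l Expolinear exponential-phase rate (1/day).
#' @param t_b Inflection offset of the expolinear curve (days after
#'   emergence).
#' @param lai_max Maximum LAI (<= 10).
#' @param seed_fill_fraction Fraction of daily biomass partitioned to grain
#'   between R5 and R7, in (0, 1].
#' @param et_coefficient Priestley-Taylor alpha.
#' @param stress_half_point Fraction of water-holding capacity at which the
#'   stress factor reaches 0.5 of its range.
#' @param grain_moisture Moisture basis for reported yield (fraction; yields
#'   are reported at 13 percent moisture).
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(rue = 1.05, k_ext = 0.6,
                          c_l = 0.16, r_l = 0.14, t_b = 22,
                          lai_max = 6, seed_fill_fraction = 0.65,
                          et_coefficient = 1.26, stress_half_point = 0.35,
                          grain_moisture = 0.13) {
  for (nm in c("rue", "k_ext", "c_l", "r_l", "t_b", "lai_max",
               "seed_fill_fraction", "et_coefficient", "stress_half_point"))
    assert_scalar(get(nm), nm, 0, Inf, strict_lower = TRUE)
  assert_scalar(lai_max, "lai_max", 0, 10, strict_lower = TRUE)
  assert_scalar(seed_fill_fraction, "seed_fill_fraction", 0, 1, strict_lower = TRUE)
  structure(list(rue = rue, k_ext = k_ext, c_l = c_l, r_l = r_l, t_b = t_b,
                 lai_max = lai_max, seed_fill_fraction = seed_fill_fraction,
                 et_coefficient = et_coefficient,
                 stress_half_point = stress_half_point,
                 grain_moisture = grain_moisture),
            class = "growth_config")
}

#' Simulation configuration: water mode and initial-moisture offset
#'
#' `potential` mode removes the water limitation entirely (stress fixed at
#' 1); `rainfed` mode runs the bucket water balance from an initial
#' plant-available water set by the satellite moisture mean shifted by
#' `init_offset` ensemble standard deviations (-1, 0 or +1).
#'
#' @param mode `"potential"` or `"rainfed"`.
#' @param init_offset Initial-moisture offset in ensemble-SD units; ignored
#'   in potential mode.
#' @return An object of class `sim_configuration`.
#' @export
sim_configuration <- function(mode = c("potential", "rainfed"),
                              init_offset = 0) {
  mode <- match.arg(mode)
  if (mode == "rainfed" && !init_offset %in% c(-1, 0, 1))
    stop("init_offset must be -1, 0 or +1")
  structure(list(mode = mode,
                 init_offset = if (mode == "rainfed") init_offset else 0,
                 label = if (mode == "potential") "potential"
                         else sprintf("rainfed%+d", init_offset)),
            class = "sim_configuration")
}

#' The four study configurations
#'
#' One potential run plus rainfed runs at -1, 0, +1 initial-moisture
#' standard deviations.
#' @return List of four [sim_configuration] objects.
#' @export
default_configurations <- function() {
  list(sim_configuration("potential"),
       sim_configuration("rainfed", -1),
       sim_configuration("rainfed", 0),
       sim_configuration("rainfed", 1))
}

#' Expolinear leaf area index
#'
#' `LAI(t) = min(lai_max, (c_l / r_l) * log(1 + exp(r_l * (t - t_b))))`:
#' exponential canopy expansion early, transitioning smoothly to a linear
#' phase with slope `c_l`, capped at `lai_max`. Non-decreasing in `t`.
#'
#' @param days_since_emergence Days since emergence (>= 0; vector allowed).
#' @param cfg A [growth_config].
#' @return LAI values.
#' @export
expolinear_lai <- function(days_since_emergence, cfg = growth_config()) {
  if (any(days_since_emergence < 0)) stop("days_since_emergence must be >= 0")
  x <- cfg$r_l * (days_since_emergence - cfg$t_b)
  softplus <- ifelse(x > 30, x, log1p(exp(x))) # overflow-safe log(1 + e^x)
  pmin(cfg$lai_max, (cfg$c_l / cfg$r_l) * softplus)
}

# Priestley-Taylor potential evapotranspiration demand (mm/day) from solar
# radiation and daily mean temperature, scaled by fractional interception.
et_demand_pt <- function(srad, tmean, fint, alpha) {
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  delta <- 4098 * es / (tmean + 237.3)^2
  gamma <- 0.067 # psychrometric constant, kPa/degC
  lambda <- 2.45 # MJ/kg
  rn <- 0.75 * srad # net radiation approximation
  pmax(0, alpha * delta / (delta + gamma) * rn / lambda * fint)
}

#' One daily step of the bucket soil-water balance
#'
#' The stress factor is evaluated on the pre-update store:
#' `stress = min(1, paw / (2 * stress_half_point * capacity))`. Actual
#' evapotranspiration is demand times stress (never more than the water
#' available), inflow above capacity leaves as runoff, and the store stays
#' in `[0, capacity]`. Water is conserved exactly:
#' `paw' - paw = precip - runoff - et_actual`.
#'
#' @param state List with `paw`, `runoff_cum`, `et_cum` (mm).
#' @param precip Precipitation (mm, >= 0).
#' @param et_demand Evapotranspiration demand (mm, >= 0).
#' @param soil A `soil_profile` (uses `paw_capacity`).
#' @param cfg A [growth_config] (uses `stress_half_point`).
#' @return List with updated `state` and the `stress` fraction applied.
#' @export
water_balance_step <- function(state, precip, et_demand, soil,
                               cfg = growth_config()) {
  if (precip < 0 || et_demand < 0) stop("precip and et_demand must be >= 0")
  cap <- soil$paw_capacity
  stress <- min(1, state$paw / (2 * cfg$stress_half_point * cap))
  et_actual <- min(et_demand * stress, state$paw + precip)
  paw_new <- state$paw + precip - et_actual
  runoff <- max(0, paw_new - cap)
  paw_new <- paw_new - runoff
  list(state = list(paw = paw_new,
                    runoff_cum = state$runoff_cum + runoff,
                    et_cum = state$et_cum + et_actual),
       stress = stress)
}

# Initial plant-available water (mm) for a rainfed run.
initial_paw <- function(soil, moisture, init_offset) {
  sm <- moisture$sm_mean + init_offset * moisture$sm_ensemble_sd
  paw <- (sm - soil$wilting_point) * soil$rootzone_depth * 1000
  min(max(paw, 0), soil$paw_capacity)
}

#' Simulate one growing season
#'
#' Daily loop from emergence to physiological maturity: Beer-law
#' interception of solar radiation by the expolinear canopy, biomass
#' accumulation at the radiation-use efficiency scaled by the water-stress
#' factor (fixed at 1 in potential mode), grain accumulating a fixed
#' fraction of daily biomass between R5 and R7, and the bucket water balance
#' driven by Priestley-Taylor demand. Yield is grain dry mass converted to
#' t/ha at the configured grain moisture.
#'
#' @param series Single-year daily weather data.frame.
#' @param stages A `stage_dates` with `reached_r7` true.
#' @param soil A `soil_profile`.
#' @param moisture A `moisture_init`.
#' @param simcfg A [sim_configuration].
#' @param cfg A [growth_config].
#' @return List: `yield_t_ha`, `biomass_t_ha`, and final `water` state.
#' @export
simulate_season <- function(series, stages, soil, moisture,
                            simcfg = sim_configuration("potential"),
                            cfg = growth_config()) {
  if (!isTRUE(stages$reached_r7)) stop("stages incomplete: season did not reach R7")
  series <- series_one_year(series)
  rainfed <- simcfg$mode == "rainfed"
  idx <- series$doy > stages$emergence & series$doy <= stages$r7
  days <- series[idx, , drop = FALSE]
  dse <- days$doy - stages$emergence

  state <- list(paw = if (rainfed) initial_paw(soil, moisture, simcfg$init_offset)
                       else 0,
                runoff_cum = 0, et_cum = 0)
  biomass <- 0; grain <- 0
  lai <- expolinear_lai(dse, cfg)
  fint <- 1 - exp(-cfg$k_ext * lai)
  tmean <- (days$tmin_c + days$tmax_c) / 2

  for (i in seq_len(nrow(days))) {
    stress <- 1
    if (rainfed) {
      demand <- et_demand_pt(days$srad_mj_m2[i], tmean[i], fint[i],
                             cfg$et_coefficient)
      step <- water_balance_step(state, days$precip_mm[i], demand, soil, cfg)
      state <- step$state
      stress <- step$stress
    }
    inc <- cfg$rue * days$srad_mj_m2[i] * fint[i] * stress # g/m2
    biomass <- biomass + inc
    if (days$doy[i] > stages$r5) grain <- grain + cfg$seed_fill_fraction * inc
  }
  dry_to_wet <- 1 / (1 - cfg$grain_moisture)
  list(yield_t_ha = grain * 0.01 * dry_to_wet, # g/m2 -> t/ha
       biomass_t_ha = biomass * 0.01,
       water = state)
}
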