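# In-code fixtures shared across the suite: hand-built weather series with
# known properties, so stage dates and water fluxes can be checked against
# hand arithmetic.

# A full-year daily series with constant (or recycled) values.
make_series <- function(tmin, tmax, precip = 0, srad = 15, year = 2001,
                        lat = 45, site_id = "T1") {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(dates)
  out <- data.frame(site_id = site_id, date = dates, year = year,
                    doy = seq_len(n),
                    tmin_c = rep_len(tmin, n), tmax_c = rep_len(tmax, n),
                    precip_mm = rep_len(precip, n),
                    srad_mj_m2 = rep_len(srad, n), stringsAsFactors = FALSE)
  attr(out, "lat") <- lat
  out
}

# Temperatures giving an exact constant daily GDU (within the clamp range).
series_with_gdu <- function(gdu, ...) {
  make_series(tmin = 10, tmax = 10 + 2 * gdu, ...)
}

# A complete stage_dates object for engine tests.
make_stages <- function(planting, emergence, r1, r5, r7) {
  structure(list(planting = planting, emergence = emergence, r1 = r1,
                 r5 = r5, r7 = r7, reached_r7 = !is.na(r7)),
            class = "stage_dates")
}

# Minimal soil/moisture pair with round numbers.
make_soil <- function(capacity = 100, wp = 0.1, porosity = 0.5,
                      sm = 0.25, sm_sd = 0.03) {
  list(soil = structure(list(paw_capacity = capacity, wilting_point = wp,
                             porosity = porosity, rootzone_depth = 1),
                        class = "soil_profile"),
       moisture = structure(list(sm_mean = sm, sm_ensemble_sd = sm_sd),
                            class = "moisture_init"))
}

# Hand-built season-result rows for the summariser.
make_results <- function(site_id, years, mgs, configs, yield, failed,
                         planting = 120) {
  g <- expand.grid(year = years, mg = mgs, config = configs,
                   stringsAsFactors = FALSE)
  data.frame(site_id = site_id, g,
             planting_doy = planting, emergence_doy = planting + 10,
             r1_doy = planting + 50, r5_doy = planting + 80,
             r7_doy = planting + 120,
             yield_t_ha = rep_len(yield, nrow(g)),
             failed = rep_len(failed, nrow(g)),
             failure_reason = ifelse(rep_len(failed, nrow(g)), "frost", "none"),
             stringsAsFactors = FALSE)
}
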