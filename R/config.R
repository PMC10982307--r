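#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, organised by stage. The defaults
#' are the study constants: GDU base/ceiling 10/30 degC, planting threshold
#' 4.4 GDU/day over a 7-day window from 1 March, 70 GDU to emergence,
#' failure rules 0 degC / 170 days / 7 t/ha cap, 75 km distance band and 16
#' clusters, and the scenario coefficients (6.1 percent set-aside, 10
#' percent wheat replacement, 7.1 t/ha wheat, 1.39 kg CO2e/kg imports,
#' 3.6 t C/ha/yr sequestration, 7:1 milk substitution).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    run = list(seed = 1L, out_dir = "results", log_level = "info",
               stages = c("simulate", "cluster", "scenarios", "trends")),
    synthetic = list(n_lat = 10L, n_lon = 4L, resolution = 2.5,
                     n_years = 5L, start_year = 1999L),
    phenology = list(gdu_base = 10, gdu_max = 30, planting_window = 7L,
                     planting_threshold = 4.4, earliest_planting = "03-01",
                     latest_planting = "06-30", emergence_gdu = 70,
                     photoperiod_critical = 13.5),
    growth = list(rue = 1.05, k_ext = 0.6, c_l = 0.16, r_l = 0.14,
                  t_b = 22, lai_max = 6, seed_fill_fraction = 0.65,
                  et_coefficient = 1.26, stress_half_point = 0.35,
                  grain_moisture = 0.13),
    failure = list(frost_threshold = 0, max_cycle_days = 170, cap_yield = 7),
    clustering = list(distance_band_km = 75, n_clusters = 16L),
    scenarios = list(setaside_ratio = 0.061, setaside_use = 0.5,
                     eligibility_yield = 3.0, wheat_replacement = 0.10,
                     wheat_yield = 7.1, europe_mean_soy_yield = 3.2,
                     brazil_soy_yield = 5.0, import_ghg_intensity = 1.39,
                     sequestration = 3.6, milk_substitution = 7,
                     protein_substitution = 1.0, substitution_fraction = 0.5)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    full <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills every unset key from [default_config], rejects
#' unknown keys, and validates each section by constructing its stage
#' object (so every type invariant is checked on load). An empty file
#' yields the all-defaults configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `pipeline_config`: the merged `raw` list plus
#'   constructed `phenology`, `growth`, `failure` and `scenario`
#'   coefficient objects.
#' @export
load_config <- function(path = NULL) {
  raw <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) raw <- merge_config(raw, user)
  }
  build <- function(section, ctor, args) {
    tryCatch(do.call(ctor, args),
             error = function(e) stop("config section '", section, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  ph <- raw$phenology
  cfg <- list(
    raw = raw,
    phenology = build("phenology", phenology_config,
                      ph[setdiff(names(ph), character(0))]),
    growth = build("growth", growth_config, raw$growth),
    failure = build("failure", failure_rules, raw$failure),
    scenarios = build("scenarios", scenario_coefficients, raw$scenarios))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize a configuration back to YAML
#'
#' Writes the raw merged configuration; loading the written file
#' reproduces the same configuration (round-trip idempotence).
#'
#' @param cfg A `pipeline_config` from [load_config].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}
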