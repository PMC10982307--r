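#' Scenario coefficient registry
#'
#' All coefficients used by the six land-use scenarios: the set-aside ratio
#' and the half of it planted, the yield-eligibility threshold, the wheat
#' replacement fraction and reference wheat yield, reference European and
#' Brazilian soybean yields, the GHG intensity of imported soybean, the
#' carbon sequestration potential of spared land (read as t carbon per ha
#' per year and converted to CO2 by 44/12), the milk and protein
#' substitution rules, protein contents, and the feed-inventory and
#' crop-intensity registries used by the animal-substitution scenarios.
#'
#' The feed-inventory and crop land/N intensities are synthetic placeholder
#' values in a config registry (editable via the packaged YAML); scenario
#' rows that depend on them are checked for structure and internal
#' consistency, not for equality with any published inventory.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `scenario_coefficients`.
#' @export
scenario_coefficients <- function(...) {
  defaults <- list(
    setaside_ratio = 0.061,
    setaside_use = 0.5,
    eligibility_yield = 3.0,       # t/ha
    wheat_replacement = 0.10,      # fraction of wheat area
    wheat_yield = 7.1,             # t/ha
    europe_mean_soy_yield = 3.2,   # t/ha
    brazil_soy_yield = 5.0,        # t/ha
    import_ghg_intensity = 1.39,   # kg CO2e per kg soybean
    sequestration = 3.6,           # t C /ha/yr on spared land
    c_to_co2 = 44 / 12,
    milk_substitution = 7,         # kg milk per kg soybean
    protein_substitution = 1.0,    # protein ratio for chicken and pork
    substitution_fraction = 0.5,   # share of new soy displacing animal protein
    protein_content = list(soybean = 36, chicken = 20, pork = 19), # g/100g
    # kg of each feed crop, and kg CO2e, per kg of animal product (synthetic
    # placeholder inventory)
    feed_inventory = list(
      chicken = list(wheat = 1.05, barley = 0.15, maize = 0.55,
                     soybean = 0.55, rapeseed = 0.08, sunflower = 0.06,
                     ghg_kg_co2e = 4.5),
      pork = list(wheat = 1.10, barley = 0.55, maize = 0.45,
                  soybean = 0.35, rapeseed = 0.10, sunflower = 0.08,
                  ghg_kg_co2e = 5.5),
      milk = list(wheat = 0.08, barley = 0.06, maize = 0.12,
                  soybean = 0.05, rapeseed = 0.03, sunflower = 0.01,
                  ghg_kg_co2e = 1.25)),
    # ha and kg fertiliser-N per tonne of feed crop (synthetic placeholders)
    crop_land_n_intensity = list(
      wheat = list(ha_per_t = 1 / 7.1, kg_n_per_t = 25),
      barley = list(ha_per_t = 0.17, kg_n_per_t = 20),
      maize = list(ha_per_t = 0.11, kg_n_per_t = 22),
      rapeseed = list(ha_per_t = 0.31, kg_n_per_t = 55),
      sunflower = list(ha_per_t = 0.42, kg_n_per_t = 18))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown coefficient(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  co <- defaults
  for (nm in c("setaside_ratio", "setaside_use", "wheat_replacement",
               "substitution_fraction"))
    assert_scalar(co[[nm]], nm, 0, 1)
  for (nm in c("eligibility_yield", "wheat_yield", "europe_mean_soy_yield",
               "brazil_soy_yield", "import_ghg_intensity", "sequestration",
               "milk_substitution"))
    assert_scalar(co[[nm]], nm, 0, Inf, strict_lower = TRUE)
  structure(co, class = "scenario_coefficients")
}

#' Read the packaged regional cluster table
#'
#' The per-cluster table of arable areas, land-use fractions, simulated
#' potential and rainfed yields, success rates and best maturity groups for
#' the sixteen agroclimatic clusters (A to P) that the scenarios consume.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A data.frame, one row per cluster.
#' @export
read_cluster_table <- function(path = system.file("extdata",
                                                  "table1_clusters.csv",
                                                  package = "eurosoy")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cluster", "arable_ha", "wheat_pct", "potential_mean",
              "rainfed_mean", "success_pct")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) stop("cluster table lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (any(tab$arable_ha <= 0)) stop("arable_ha must be positive")
  tab
}

yield_col <- function(yield_column) {
  switch(yield_column,
         rainfed = "rainfed_mean",
         potential = "potential_mean",
         stop("unknown yield column: ", yield_column))
}

#' Clusters eligible for soybean expansion
#'
#' Clusters whose chosen yield (rainfed or potential) meets the eligibility
#' threshold and whose rainfed crop success is above zero.
#'
#' @param table Cluster table (see [read_cluster_table]).
#' @param yield_column `"rainfed"` or `"potential"`.
#' @param threshold Eligibility yield (t/ha, default 3).
#' @return The subset of eligible cluster rows.
#' @export
eligible_clusters <- function(table, yield_column = "rainfed",
                              threshold = 3.0) {
  if (nrow(table) == 0L) stop("cluster table is empty")
  col <- yield_col(yield_column)
  table[table[[col]] >= threshold & table$success_pct > 0, , drop = FALSE]
}

#' Set-aside scenario: soy on half the set-aside of eligible regions
#'
#' Plants soybean on `setaside_ratio * setaside_use` (3.05 percent at
#' defaults) of the arable area of every eligible cluster; production is the
#' same sum product weighted by each cluster's own yield in the chosen
#' column.
#'
#' @inheritParams eligible_clusters
#' @param coeffs A [scenario_coefficients].
#' @return List with `area_mha` and `production_mt`.
#' @export
scenario_setaside <- function(table, coeffs = scenario_coefficients(),
                              yield_column = "rainfed") {
  el <- eligible_clusters(table, yield_column, coeffs$eligibility_yield)
  if (nrow(el) == 0L) {
    warning("no eligible clusters; set-aside scenario is empty")
    return(list(area_mha = 0, production_mt = 0))
  }
  frac <- coeffs$setaside_ratio * coeffs$setaside_use
  area_mha <- frac * sum(el$arable_ha) / 1e6
  production_mt <- frac * sum(el$arable_ha * el[[yield_col(yield_column)]]) / 1e6
  list(area_mha = area_mha, production_mt = production_mt)
}

#' Wheat-replacement scenario: soy on 10 percent of eligible wheat area
#'
#' Converts `wheat_replacement` of the wheat acreage of every eligible
#' cluster to soybean. At current yields (`yield_column = "rainfed"`) the
#' new soy produces at the European mean soybean yield; at potential yields
#' each cluster produces at its own potential yield. Displaced wheat is the
#' converted area times the reference wheat yield.
#'
#' @inheritParams scenario_setaside
#' @return List with `area_mha`, `production_mt`, `displaced_wheat_mt`.
#' @export
scenario_wheat_replacement <- function(table,
                                       coeffs = scenario_coefficients(),
                                       yield_column = "rainfed") {
  if (any(is.na(table$wheat_pct))) stop("wheat fraction missing for some clusters")
  el <- eligible_clusters(table, yield_column, coeffs$eligibility_yield)
  wheat_area_ha <- el$arable_ha * el$wheat_pct / 100
  area_mha <- coeffs$wheat_replacement * sum(wheat_area_ha) / 1e6
  production_mt <- if (yield_column == "rainfed") {
    area_mha * coeffs$europe_mean_soy_yield
  } else {
    coeffs$wheat_replacement *
      sum(wheat_area_ha * el$potential_mean) / 1e6
  }
  list(area_mha = area_mha, production_mt = production_mt,
       displaced_wheat_mt = area_mha * coeffs$wheat_yield)
}

#' Import substitution of European soybean production
#'
#' European production replaces soybean imported from Brazil one for one:
#' imports fall by the production, production-and-transport GHG falls by
#' the import GHG intensity times production, and Brazilian cultivation
#' area is spared at the Brazilian yield.
#'
#' @param production_mt European soybean production (Mt, >= 0).
#' @param coeffs A [scenario_coefficients].
#' @return List with `imported_soybean_mt` (negative),
#'   `production_ghg_mt_co2e` (negative) and `brazil_land_spared_mha`.
#' @export
import_substitution <- function(production_mt,
                                coeffs = scenario_coefficients()) {
  stopifnot(production_mt >= 0)
  list(imported_soybean_mt = -production_mt,
       production_ghg_mt_co2e = -production_mt * coeffs$import_ghg_intensity,
       brazil_land_spared_mha = production_mt / coeffs$brazil_soy_yield)
}

#' Carbon opportunity cost of net spared land
#'
#' Sequestration forgone or gained on the net land-area change:
#' `-net_spared * sequestration * 44/12` (13.2 t CO2e/ha/yr at defaults).
#' Negative values are savings; a net cropland expansion (negative spared
#' land) flips the sign.
#'
#' @param net_spared_mha Net land spared (Mha; may be negative).
#' @param coeffs A [scenario_coefficients].
#' @return Carbon opportunity cost in Mt CO2e per year.
#' @export
carbon_opportunity_cost <- function(net_spared_mha,
                                    coeffs = scenario_coefficients()) {
  -net_spared_mha * coeffs$sequestration * coeffs$c_to_co2
}

#' Animal-protein substitution of soybean
#'
#' Splits the soybean destined for diets equally across chicken, pork and
#' milk: chicken and pork are displaced 1:1 on protein (via the protein
#' contents), milk by the fixed kg-milk-per-kg-soy ratio. Avoided feed
#' crops, spared land, fertiliser-N and production GHG follow from the
#' feed-inventory and crop-intensity registries (avoided soybean feed is
#' treated like avoided imports: Brazilian land and GHG intensity).
#'
#' @param soy_for_diet_mt Soybean going to human diets (Mt, >= 0).
#' @param coeffs A [scenario_coefficients].
#' @return List with `products_mt` (avoided chicken/pork/milk),
#'   `feed_mt` (avoided feed per crop), `spared_land_mha`,
#'   `fertiliser_n_mt`, `production_ghg_mt_co2e` (negative = saving).
#' @export
animal_substitution <- function(soy_for_diet_mt,
                                coeffs = scenario_coefficients()) {
  stopifnot(soy_for_diet_mt >= 0)
  pc <- coeffs$protein_content
  for (k in c("soybean", "chicken", "pork"))
    if (is.null(pc[[k]])) stop("missing protein content for: ", k)
  third <- soy_for_diet_mt / 3
  products <- c(
    chicken = third * coeffs$protein_substitution * pc$soybean / pc$chicken,
    pork = third * coeffs$protein_substitution * pc$soybean / pc$pork,
    milk = third * coeffs$milk_substitution)

  crops <- c("wheat", "barley", "maize", "soybean", "rapeseed", "sunflower")
  feed <- stats::setNames(numeric(length(crops)), crops)
  ghg <- 0
  for (p in names(products)) {
    inv <- coeffs$feed_inventory[[p]]
    if (is.null(inv)) stop("missing feed inventory entry for: ", p)
    for (cr in crops) {
      if (is.null(inv[[cr]])) stop("missing feed inventory entry for: ",
                                   p, "/", cr)
      feed[[cr]] <- feed[[cr]] + products[[p]] * inv[[cr]]
    }
    ghg <- ghg + products[[p]] * inv$ghg_kg_co2e
  }
  land <- 0; fert_n <- 0
  for (cr in setdiff(crops, "soybean")) {
    ci <- coeffs$crop_land_n_intensity[[cr]]
    if (is.null(ci)) stop("missing crop intensity entry for: ", cr)
    land <- land + feed[[cr]] * ci$ha_per_t      # Mt * ha/t = Mha
    fert_n <- fert_n + feed[[cr]] * ci$kg_n_per_t / 1e3 # Mt crop -> Mt N
  }
  soy_imp <- import_substitution(feed[["soybean"]], coeffs)
  list(products_mt = products,
       feed_mt = feed,
       spared_land_mha = land + soy_imp$brazil_land_spared_mha,
       fertiliser_n_mt = fert_n,
       production_ghg_mt_co2e = -(ghg) + soy_imp$production_ghg_mt_co2e)
}

empty_ledger_row <- function(scenario) {
  data.frame(scenario = scenario, european_soybean = 0, imported_soybean = 0,
             displaced_wheat = 0, barley_feed = 0, maize_feed = 0,
             rapeseed_feed = 0, sunflower_feed = 0, cropland_area = 0,
             fertiliser_n = 0, production_ghg = 0,
             carbon_opportunity_cost = 0, stringsAsFactors = FALSE)
}

#' Assemble a scenario ledger row
#'
#' Collects the components of one scenario into a single ledger row with
#' the sign conventions of the scenario table: savings negative, new
#' production and land demand positive. `cropland_area` nets the land
#' needed to compensate displaced wheat against Brazilian land spared by
#' import substitution and any feed-crop land spared; the carbon
#' opportunity cost is the sequestration forgone (or gained) on that net
#' area.
#'
#' @param scenario Scenario id (e.g. `"Sc-3"`).
#' @param components Named list with any of `european_soybean_mt`,
#'   `displaced_wheat_mt`, `import` (from [import_substitution]), `animal`
#'   (from [animal_substitution]).
#' @param coeffs A [scenario_coefficients].
#' @return A one-row data.frame ledger.
#' @export
assemble_ledger <- function(scenario, components,
                            coeffs = scenario_coefficients()) {
  row <- empty_ledger_row(scenario)
  row$european_soybean <- components$european_soybean_mt %||% 0
  wheat_displaced <- components$displaced_wheat_mt %||% 0
  imp <- components$import
  ani <- components$animal

  spared <- 0
  if (!is.null(imp)) {
    row$imported_soybean <- row$imported_soybean + imp$imported_soybean_mt
    row$production_ghg <- row$production_ghg + imp$production_ghg_mt_co2e
    spared <- spared + imp$brazil_land_spared_mha
  }
  if (!is.null(ani)) {
    row$imported_soybean <- row$imported_soybean - ani$feed_mt[["soybean"]]
    wheat_displaced <- wheat_displaced - ani$feed_mt[["wheat"]]
    row$barley_feed <- -ani$feed_mt[["barley"]]
    row$maize_feed <- -ani$feed_mt[["maize"]]
    row$rapeseed_feed <- -ani$feed_mt[["rapeseed"]]
    row$sunflower_feed <- -ani$feed_mt[["sunflower"]]
    row$fertiliser_n <- -ani$fertiliser_n_mt
    row$production_ghg <- row$production_ghg + ani$production_ghg_mt_co2e
    # animal spared land already includes its soy-feed Brazilian land
    spared <- spared + ani$spared_land_mha
  }
  row$displaced_wheat <- wheat_displaced
  # land to compensate the (net) displaced wheat elsewhere, at the
  # reference wheat yield; netted against all spared land
  compensation_mha <- max(0, wheat_displaced) / coeffs$wheat_yield
  row$cropland_area <- compensation_mha - spared
  row$carbon_opportunity_cost <- carbon_opportunity_cost(-row$cropland_area,
                                                         coeffs)
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run all six scenarios on a cluster table
#'
#' Sc-1/Sc-2: soybean on half the set-aside of eligible clusters at current
#' (cluster rainfed) or potential (cluster potential) yields. Sc-3/Sc-4:
#' 10 percent of eligible wheat area converted to soy at current (European
#' mean) or cluster potential yields, displacing wheat. Sc-5/Sc-6: as
#' Sc-3/Sc-4 with half the production displacing animal protein (chicken,
#' pork, milk in equal thirds) instead of imports.
#'
#' @param table Cluster table (default the packaged fixture).
#' @param coeffs A [scenario_coefficients].
#' @return A six-row ledger data.frame, one row per scenario.
#' @export
run_scenarios <- function(table = read_cluster_table(),
                          coeffs = scenario_coefficients()) {
  rows <- list()
  for (v in c("rainfed", "potential")) {
    id <- if (v == "rainfed") "Sc-1" else "Sc-2"
    sa <- scenario_setaside(table, coeffs, v)
    rows[[id]] <- assemble_ledger(id, list(
      european_soybean_mt = sa$production_mt,
      import = import_substitution(sa$production_mt, coeffs)), coeffs)
  }
  for (v in c("rainfed", "potential")) {
    id <- if (v == "rainfed") "Sc-3" else "Sc-4"
    wr <- scenario_wheat_replacement(table, coeffs, v)
    rows[[id]] <- assemble_ledger(id, list(
      european_soybean_mt = wr$production_mt,
      displaced_wheat_mt = wr$displaced_wheat_mt,
      import = import_substitution(wr$production_mt, coeffs)), coeffs)
  }
  for (v in c("rainfed", "potential")) {
    id <- if (v == "rainfed") "Sc-5" else "Sc-6"
    wr <- scenario_wheat_replacement(table, coeffs, v)
    half <- coeffs$substitution_fraction * wr$production_mt
    rows[[id]] <- assemble_ledger(id, list(
      european_soybean_mt = wr$production_mt,
      displaced_wheat_mt = wr$displaced_wheat_mt,
      import = import_substitution(wr$production_mt - half, coeffs),
      animal = animal_substitution(half, coeffs)), coeffs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a ledger for display
#'
#' Full precision is carried internally; display rounding (nearest integer
#' for Mt and Mt CO2e, one decimal for Mha) happens only at serialization.
#'
#' @param ledger Ledger data.frame from [run_scenarios].
#' @return The rounded ledger.
#' @export
format_ledger <- function(ledger) {
  mt_cols <- c("european_soybean", "imported_soybean", "displaced_wheat",
               "production_ghg", "carbon_opportunity_cost")
  one_dp <- c("barley_feed", "maize_feed", "rapeseed_feed", "sunflower_feed",
              "cropland_area", "fertiliser_n")
  for (cl in mt_cols) ledger[[cl]] <- round(ledger[[cl]])
  for (cl in one_dp) ledger[[cl]] <- round(ledger[[cl]], 1)
  ledger
}
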