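tab <- read_cluster_table()
co <- scenario_coefficients()

test_that("eligibility selects the documented cluster sets", {
  expect_setequal(eligible_clusters(tab, "rainfed", 3)$cluster,
                  c("E", "F", "G", "I"))
  expect_setequal(eligible_clusters(tab, "potential", 3)$cluster,
                  c("D", "E", "F", "G", "H", "I", "J", "K"))
  expect_equal(nrow(eligible_clusters(tab, "rainfed", 100)), 0)
  expect_error(eligible_clusters(tab, "observed", 3), "unknown yield column")
  # raising the threshold never adds clusters
  sizes <- vapply(seq(0, 8, by = 0.5), function(th)
    nrow(eligible_clusters(tab, "rainfed", th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the set-aside scenario is the documented sum product", {
  one <- data.frame(cluster = "X", arable_ha = 1e7, wheat_pct = 30,
                    potential_mean = 5, rainfed_mean = 4, success_pct = 90)
  sa <- scenario_setaside(one, co, "rainfed")
  expect_equal(sa$area_mha, 10 * 0.061 * 0.5)    # 0.305 Mha
  expect_equal(sa$production_mt, 10 * 0.061 * 0.5 * 4) # 1.22 Mt

  sa_fix <- scenario_setaside(tab, co, "rainfed")
  expect_equal(sa_fix$area_mha, 3.65, tolerance = 0.01)
  expect_equal(sa_fix$production_mt, 12.7, tolerance = 0.01)

  none <- scenario_coefficients(setaside_use = 0)
  expect_equal(scenario_setaside(tab, none, "rainfed")$production_mt, 0)
})

test_that("wheat replacement reproduces the published areas and displacement", {
  wr3 <- scenario_wheat_replacement(tab, co, "rainfed")
  wr4 <- scenario_wheat_replacement(tab, co, "potential")
  expect_equal(round(wr3$area_mha, 1), 3.6)
  expect_equal(round(wr4$area_mha, 1), 4.8)
  expect_equal(wr3$displaced_wheat_mt, wr3$area_mha * 7.1) # exact identity
  expect_equal(round(wr3$displaced_wheat_mt), 26)
  expect_equal(round(wr4$displaced_wheat_mt), 34)
  expect_equal(wr3$production_mt, wr3$area_mha * 3.2)

  bad <- tab; bad$wheat_pct[3] <- NA
  expect_error(scenario_wheat_replacement(bad, co, "rainfed"), "wheat fraction")
})

test_that("import substitution converts production to GHG and spared land", {
  z <- import_substitution(0, co)
  expect_equal(unlist(z), c(imported_soybean_mt = 0,
                            production_ghg_mt_co2e = 0,
                            brazil_land_spared_mha = 0))
  wr3 <- scenario_wheat_replacement(tab, co, "rainfed")
  imp <- import_substitution(wr3$production_mt, co)
  expect_equal(imp$production_ghg_mt_co2e, -1.39 * wr3$production_mt) # exact
  expect_equal(round(imp$production_ghg_mt_co2e), -16)
  expect_equal(import_substitution(9, co)$brazil_land_spared_mha, 1.8)
})

test_that("carbon opportunity cost uses 3.6 t C/ha/yr times 44/12", {
  expect_equal(carbon_opportunity_cost(1.8, co), -1.8 * 3.6 * 44 / 12)
  expect_equal(round(carbon_opportunity_cost(1.8, co)), -24)
  expect_equal(round(carbon_opportunity_cost(6.5, co)), -86)
  expect_equal(round(carbon_opportunity_cost(15, co)), -198)
  expect_equal(carbon_opportunity_cost(0, co), 0)
  expect_gt(carbon_opportunity_cost(-1, co), 0) # expansion flips the sign
})

test_that("animal substitution follows the milk and protein rules", {
  z <- animal_substitution(0, co)
  expect_true(all(unlist(z[c("products_mt", "feed_mt")]) == 0))
  a <- animal_substitution(1, co)
  expect_equal(unname(a$products_mt["milk"]), 7 / 3) # 7 kg milk per kg soy
  expect_equal(unname(a$products_mt["chicken"]),
               (1 / 3) * co$protein_content$soybean / co$protein_content$chicken)
  expect_equal(unname(a$products_mt["pork"]),
               (1 / 3) * co$protein_content$soybean / co$protein_content$pork)
  expect_true(a$production_ghg_mt_co2e < 0)
  expect_true(a$fertiliser_n_mt > 0)

  broken <- co; broken$feed_inventory$milk$maize <- NULL
  expect_error(animal_substitution(1, broken), "milk/maize")
})

test_that("the six ledgers nest and balance as documented", {
  led <- run_scenarios(tab, co)
  expect_equal(led$scenario, paste0("Sc-", 1:6))
  # Sc-5/Sc-6 European soybean equals Sc-3/Sc-4's
  expect_equal(led$european_soybean[5], led$european_soybean[3])
  expect_equal(led$european_soybean[6], led$european_soybean[4])
  # Sc-1/2: no wheat displaced, imports mirror production exactly
  expect_equal(led$displaced_wheat[1:2], c(0, 0))
  expect_equal(led$imported_soybean[1:2], -led$european_soybean[1:2])
  expect_equal(led$production_ghg[1:4], -1.39 * led$european_soybean[1:4])
  # savings are negative, new production positive
  expect_true(all(led$european_soybean > 0))
  expect_true(all(led$imported_soybean < 0))
  expect_true(all(led$production_ghg < 0))
  expect_true(all(led[5:6, c("barley_feed", "maize_feed", "rapeseed_feed",
                             "sunflower_feed", "fertiliser_n")] < 0))
  # COC is the sequestration coefficient applied to the net area row
  expect_equal(led$carbon_opportunity_cost,
               led$cropland_area * 3.6 * 44 / 12)
  # full precision internally; display rounding only at serialization
  expect_false(all(led$european_soybean == round(led$european_soybean)))
  fl <- format_ledger(led)
  expect_true(all(fl$european_soybean == round(fl$european_soybean)))
  expect_equal(fl$cropland_area, round(fl$cropland_area, 1))
})

test_that("a zero-component ledger row is all zero", {
  row <- assemble_ledger("Sc-0", list(), co)
  expect_true(all(row[, -1] == 0))
})
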