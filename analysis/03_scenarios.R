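#!/usr/bin/env Rscript
# Stage 3: the six environmental-savings scenarios.
#
# Converts the packaged regional cluster table (arable areas, wheat
# fractions, potential and rainfed yields for clusters A-P) into the six
# scenario ledgers: soybean on half the set-aside of eligible regions
# (Sc-1/Sc-2), 10% of wheat area replaced by soy where >= 3 t/ha is
# achievable (Sc-3/Sc-4), and the wheat-replacement scenarios with half the
# soy displacing chicken, pork and milk (Sc-5/Sc-6). Writes
# results/scenario_ledgers.csv.

suppressMessages(library(eurosoy))
dir.create("results", showWarnings = FALSE)

tab <- read_cluster_table()
coeffs <- scenario_coefficients()

cat("clusters eligible at >= 3 t/ha rainfed: ",
    paste(eligible_clusters(tab, "rainfed")$cluster, collapse = " "), "\n")
cat("clusters eligible at >= 3 t/ha potential:",
    paste(eligible_clusters(tab, "potential")$cluster, collapse = " "), "\n")

wr3 <- scenario_wheat_replacement(tab, coeffs, "rainfed")
wr4 <- scenario_wheat_replacement(tab, coeffs, "potential")
cat(sprintf("wheat-replacement soy area: %.1f Mha (current) / %.1f Mha (potential)\n",
            wr3$area_mha, wr4$area_mha))
cat(sprintf("displaced wheat: %.0f / %.0f Mt\n",
            wr3$displaced_wheat_mt, wr4$displaced_wheat_mt))
cat(sprintf("import GHG avoided at current yields: %.0f Mt CO2e\n",
            -import_substitution(wr3$production_mt, coeffs)$production_ghg_mt_co2e))

ledger <- run_scenarios(tab, coeffs)
write.csv(format_ledger(ledger), "results/scenario_ledgers.csv",
          row.names = FALSE)
cat("\nscenario ledgers (display rounding):\n")
print(format_ledger(ledger))
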