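#!/usr/bin/env Rscript
# Sweep the radiation-use efficiency and seed-fill fraction over the
# continental archetype and report mean potential yields of the best
# maturity group. Used once to pick growth_config() defaults that place
# continental potential yields in the 3-5 t/ha range; rerun after any
# change to the archetypes or phenology targets.

suppressMessages(library(eurosoy))

grid1 <- data.frame(site_id = "S1", lat = 47, lon = 15)
w <- gen_weather(default_archetypes()$continental, 10, seed = 3, lat = 47)
soil <- gen_soil(11)

for (rue in c(0.9, 1.05, 1.2)) {
  for (sff in c(0.55, 0.65, 0.75)) {
    gc <- growth_config(rue = rue, seed_fill_fraction = sff)
    res <- run_factorial(grid1, list(S1 = w), list(S1 = soil),
                         configs = list(sim_configuration("potential")),
                         growth_cfg = gc)
    best <- max(tapply(res$yield_t_ha, res$mg, mean))
    cat(sprintf("rue %.2f  seed_fill %.2f  -> best-MG potential %.2f t/ha\n",
                rue, sff, best))
  }
}
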