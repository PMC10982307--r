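# Scenario coefficient registry. Values mirror scenario_coefficients()
# defaults; the feed inventory and crop intensities are synthetic
# placeholders (a config registry, not published inventory data).
setaside_ratio: 0.061
setaside_use: 0.5
eligibility_yield: 3.0
wheat_replacement: 0.10
wheat_yield: 7.1
europe_mean_soy_yield: 3.2
brazil_soy_yield: 5.0
import_ghg_intensity: 1.39
sequestration: 3.6
milk_substitution: 7
protein_substitution: 1.0
substitution_fraction: 0.5
protein_content:
  soybean: 36
  chicken: 20
  pork: 19
feed_inventory:
  chicken: {wheat: 1.05, barley: 0.15, maize: 0.55, soybean: 0.55, rapeseed: 0.08, sunflower: 0.06, ghg_kg_co2e: 4.5}
  pork: {wheat: 1.10, barley: 0.55, maize: 0.45, soybean: 0.35, rapeseed: 0.10, sunflower: 0.08, ghg_kg_co2e: 5.5}
  milk: {wheat: 0.08, barley: 0.06, maize: 0.12, soybean: 0.05, rapeseed: 0.03, sunflower: 0.01, ghg_kg_co2e: 1.25}
crop_land_n_intensity:
  wheat: {ha_per_t: 0.1408, kg_n_per_t: 25}
  barley: {ha_per_t: 0.17, kg_n_per_t: 20}
  maize: {ha_per_t: 0.11, kg_n_per_t: 22}
  rapeseed: {ha_per_t: 0.31, kg_n_per_t: 55}
  sunflower: {ha_per_t: 0.42, kg_n_per_t: 18}
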