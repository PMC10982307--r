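---
title: "Models and methods behind eurosoy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eurosoy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`eurosoy` estimates where in Europe soybean could be grown, how much it
could yield under radiation-, temperature- and water-limited conditions,
and what a set of stylised land-use scenarios built on those yields would
mean for production, cropland, fertiliser nitrogen and greenhouse-gas
accounting. This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was open.

## Thermal-time phenology

Development is driven by growing degree units (GDU). For a day with
minimum and maximum temperature $T_{min}, T_{max}$,

$$\mathrm{GDU} = \max\!\left(0,\;
  \frac{\mathrm{clamp}(T_{max},10,30)+\mathrm{clamp}(T_{min},10,30)}{2}-10\right),$$

with base 10 degC and ceiling 30 degC, so daily GDU lies in [0, 20].

**Planting** is adaptive: the first day from 1 March on which the trailing
7-day mean GDU strictly exceeds 4.4 GDU/day. The window is causal (the
seven days ending today) because a planting decision can only use weather
already observed. The rule needs a termination bound; we declare "no
planting" after 30 June, late enough that any season still worth planting
in these latitudes has already started.

**Emergence** occurs at 70 GDU accumulated after planting; at the
threshold accumulation rate this takes just under 16 days.

**Reproductive stages.** The study this package operationalises used an
ensemble of two physiological models and a machine-learning member, none
of whose internals are published in reproducible form. We therefore use a
single transparent thermal-time model: each maturity group (0000 earliest
to III latest) carries cumulative GDU targets from emergence to flowering
(R1), start of seed fill (R5) and physiological maturity (R7), and daily
GDU is multiplied by a photoperiod modifier
$\max(0,\,1 - s\,(\mathrm{daylength}-13.5)_+)$ whose sensitivity $s$
increases toward later groups. Daylength uses the standard
solar-declination formula (civil daylength). The default targets
(R7 = 750 to 1290 GDU in steps of 90) are editable coefficients chosen so
that early groups mature in maritime summers while group III requires a
Mediterranean season; they are judged by the model's ordering properties
-- stages strictly ordered, R7 non-decreasing in maturity group, a uniform
+1 degC warming never delaying any stage -- rather than by calibration to
trial data, which this package does not attempt.

## Growth and the water balance

Canopy expansion follows the expolinear form
$L(t) = \min\!\big(L_{max},\,(c_L/r_L)\,\ln(1+e^{r_L (t-t_b)})\big)$:
exponential early growth rolling smoothly into a linear phase of slope
$c_L$, capped at $L_{max}$. Interception is Beer's law with extinction
coefficient 0.6, and biomass accumulates as intercepted radiation times a
radiation-use efficiency (RUE, g/MJ), multiplied by a water-stress factor.
Grain receives a fixed fraction of daily biomass between R5 and R7 and is
reported at 13% moisture (the source tables give Mg/ha without stating a
basis, so the convention is stated here and configurable).

The soil is a single bucket of plant-available water (PAW) over a 1 m root
zone. Each day, pre-update stress is
$\min(1, \mathrm{PAW}/(2\,h\,C))$ with capacity $C$ and half-point
fraction $h$ (default 0.35); actual evapotranspiration is
Priestley-Taylor demand (alpha 1.26, net radiation 0.75 of solar, scaled
by fractional interception) times stress, never more than the water
present; inflow above capacity runs off. The update conserves water
exactly and is audited to numerical tolerance in the tests. No published
stress function or ET scheme accompanies the source growth model, so
these standard formulations are the package's own choices.

Rainfed runs start from a satellite-style root-zone moisture estimate:
initial PAW is $(\theta_0 + k\sigma - \theta_{wp})\times 1000$ mm clamped
to $[0, C]$, with $k \in \{-1, 0, +1\}$ ensemble standard deviations
giving three initial-condition members. Potential runs fix stress at 1
and ignore water entirely.

Default growth coefficients (RUE 1.05 g/MJ, seed-fill fraction 0.65) were
picked once with the shipped sweep (`scripts/tune_growth.R`) so that the
continental archetype's best-maturity-group potential yield falls in the
3-5 t/ha range; they are defaults, not measurements.

## Failure rules and the factorial

A site-season fails if planting never occurred, if any day between
emergence and R7 has mean temperature below 0 degC, or if planting to R7
exceeds 170 days (strictly). A season whose cycle is still incomplete
when the calendar year ends is classified overlong -- the cycle could not
be completed, which is the substance of the duration rule. Frost and
duration are applied to potential runs too: the rules describe crop
survival, not water supply. Failed seasons score 0 t/ha; successful
yields are capped at 7 t/ha per season (the cap is applied before any
averaging, a choice the sources leave open). The engine enumerates the
full sites x years x maturity groups x configurations product -- 4
configurations: one potential plus three rainfed initial conditions --
with no hidden randomness, so reruns are bit-identical. The full
published design (4,036 sites x 20 years x 7 x 4 = 2,260,160 runs; 560
per site) is verified as count arithmetic; executed grids in tests and
the analysis scripts are smaller (tens of sites, 2-5 years), which keeps
the whole suite and workflow in seconds-to-minutes on one CPU.

## Regionalization

Each site is summarised by 15 statistics: mean rainfed yield per maturity
group (20 years x 3 initial conditions, failures as zeros), success rate
per group (share of years reaching R7), and mean planting day (planting is
shared across groups). Sites that never plant get the day recoded to 366
before normalisation -- no planting is the extreme of lateness.

Clustering is bottom-up Ward (minimum variance, squared Euclidean
distances, Lance-Williams update) after min-max normalisation of every
variable, with merges restricted to pairs adjacent in a binary spatial
graph: an edge wherever the haversine distance (mean Earth radius
6371 km; the sources name no metric) is within the 75 km band, which on a
0.5-degree grid connects immediate neighbours. The constrained
agglomeration is implemented in the package because no installed R
package provides connectivity-constrained Ward; with a fully connected
graph it reproduces classic Ward (`hclust`, method `ward.D` on squared
distances), which the tests use as an independent check. If the graph has
more connected components than requested clusters, each extra component
becomes its own cluster with a warning (islands are otherwise
unmergeable). Constant variables are dropped with a warning. Ties in the
"largest median yield" choice of best maturity group break toward the
earlier group (lower risk). Cluster evaluation uses the adjusted Rand
index, never raw label identities. The per-cluster table reports pooled
across-site mean and standard deviation of the best group's yields;
whether spatial and temporal variation should be pooled is ambiguous in
the source figures, and the pooled choice is stated here.

## Scenario accounting

The six ledgers consume a per-cluster table (the packaged
`table1_clusters.csv` transcribes the published cluster description) and
a coefficient registry. Eligibility everywhere means cluster yield at or
above 3 t/ha with nonzero success, using the rainfed column for
"current" variants and the potential column for "potential" variants
(the potential reading adds clusters D, H, J, K and reproduces the
published 4.8 Mha).

* **Sc-1/Sc-2 (set-aside):** soy on 50% of a 6.1% set-aside ratio of
  eligible arable land; production is the sum product with cluster
  yields. The published Sc-1 (9 Mt) and Sc-2 (13 Mt) productions cannot
  both be derived from the cluster table under any single reading of
  "current or potential yields" (cluster-rainfed weighting gives
  ~12.7 Mt, potential ~24 Mt); the engine computes the sum product as
  stated and this discrepancy is documented rather than forced.
* **Sc-3/Sc-4 (wheat replacement):** 10% of eligible wheat acreage
  converts to soy (3.6 / 4.8 Mha). Current-yield production uses the
  European mean yield of 3.2 t/ha -- the only reading that approaches
  the published ~11 Mt -- while the potential variant uses cluster
  potential yields. Displaced wheat is area times 7.1 t/ha exactly.
* **Import substitution:** each tonne of European soy replaces a tonne
  of Brazilian imports at 1.39 kg CO2e/kg and spares land at 5 t/ha.
* **Carbon opportunity cost:** net spared land sequesters
  3.6 t of **carbon** per ha per year, converted by 44/12 to 13.2
  t CO2e/ha/yr. The carbon (not CO2) reading is deliberate: it alone
  reproduces the published COC pairs (1.8 Mha to 24, 6.5 to 86, 15 to
  198 Mt CO2e). It is overridable in the registry.
* **Sc-5/Sc-6 (diet shift):** European soy equals Sc-3/Sc-4; half
  displaces animal protein in equal thirds -- chicken and pork 1:1 on
  protein (via configurable protein contents), milk at 7 kg per kg soy.
  Avoided feed, land, fertiliser-N and GHG follow from a feed-inventory
  and crop-intensity registry whose values are synthetic placeholders
  (the underlying LCA database is not reproduced here), so these rows
  are validated for structure, nesting and sign conventions only.

Ledgers carry full precision; rounding (integer Mt and Mt CO2e, one
decimal Mha) happens only at serialization.

## Synthetic inputs

The generators exist so every downstream stage is testable without
proprietary weather, satellite soil-moisture or statistical-office
downloads. Weather is monthly climatology interpolated by its first
annual Fourier harmonic, plus a Gaussian yearly offset and an AR(1) daily
anomaly (rho 0.7, sd 1.8 degC) shared by tmin and tmax so the diurnal
range follows the climatology (bounded to (0, 24] degC); precipitation is
Bernoulli-gamma (shape 0.75) reproducing monthly totals in expectation;
radiation is a solstice-peaked sinusoid with mild lognormal noise and
wet-day dimming. Four packaged archetypes (maritime, continental,
Mediterranean, sub-arctic) are stylised, not calibrated; their defining
property is qualitative: warm-season thermal time ordered Mediterranean >
continental > maritime > sub-arctic, and a sub-arctic July too cool
(maximum below 15 degC) for the planting rule, giving 0% full-pipeline
success there. Soil draws porosity, wilting point and an initial moisture
lying between them; capacity is 55% of the wilting-to-porosity span over
a 1 m root zone. National yield series are linear trends plus Gaussian
noise floored at zero.

What the generators do **not** emulate: spatial correlation of weather
between sites (each site is independent -- the source data's mapping of
station observations to grid centroids is unstated), heat waves and dry
spells beyond what AR(1) and Bernoulli-gamma produce, elevation, and any
real geography. Passing tests therefore demonstrate correct model
mechanics and faithful scenario arithmetic, not skill against observed
European yields.

## Numerical choices and degenerate inputs

Softplus in the expolinear curve switches to its linear asymptote beyond
$e^{30}$ to avoid overflow. Every generator routes randomness through a
local RNG restore, making it a pure function of its seed. The planting
threshold is a strict inequality (a window averaging exactly 4.4 never
plants). Empty eligible sets in scenarios return zeros with a warning;
a constant yield series fits slope 0 with an undefined trend p-value
handled by the caller; Pearson correlation of a constant validation
vector is reported `NA` while the other metrics are still returned; a
negative yield gap (observed above water-limited) is returned with an
out-of-range annotation rather than clamped.

## Limitations

No nitrogen budget, pests, CO2 fertilisation or double cropping; a single
bucket layer rather than a profile; phenology is a proxy for the original
unpublished ensemble and inherits none of its trained skill; scenario
rows that depend on the placeholder feed inventory are structural
illustrations, not estimates. The trend/gap utilities operate on
synthetic series; reproducing the published validation statistics would
require the original trial supplement, which is out of scope.
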