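test_that("expolinear LAI matches its analytic values", {
  cfg <- growth_config(c_l = 0.1, r_l = 0.2, t_b = 10, lai_max = 10)
  expect_equal(expolinear_lai(10, cfg), 0.5 * log(2))
  expect_equal(expolinear_lai(30, cfg), 0.5 * log(1 + exp(4)))
  capped <- growth_config(c_l = 0.1, r_l = 0.2, t_b = 10, lai_max = 1.5)
  expect_equal(expolinear_lai(30, capped), 1.5)
  # asymptotic slope approaches c_l before the cap engages
  t <- 60:61
  slope <- diff(expolinear_lai(t, cfg))
  expect_equal(slope, 0.1, tolerance = 1e-3)
  # non-decreasing everywhere
  lai <- expolinear_lai(seq(0, 120, by = 0.5), cfg)
  expect_true(all(diff(lai) >= 0))
  expect_error(expolinear_lai(-1, cfg), ">= 0")
})

test_that("the bucket water balance matches hand-evaluated steps", {
  soil <- make_soil(capacity = 100)$soil
  cfg <- growth_config(stress_half_point = 0.5)
  st0 <- list(paw = 100, runoff_cum = 0, et_cum = 0)

  full <- water_balance_step(st0, precip = 20, et_demand = 0, soil, cfg)
  expect_equal(full$state$paw, 100)
  expect_equal(full$state$runoff_cum, 20)

  dry <- water_balance_step(list(paw = 0, runoff_cum = 0, et_cum = 0),
                            0, 5, soil, cfg)
  expect_equal(dry$stress, 0)
  expect_equal(dry$state$paw, 0)
  expect_equal(dry$state$et_cum, 0)

  mid <- water_balance_step(list(paw = 50, runoff_cum = 0, et_cum = 0),
                            10, 5, soil, cfg)
  expect_equal(mid$stress, 0.5)
  expect_equal(mid$state$et_cum, 2.5)
  expect_equal(mid$state$paw, 57.5)

  expect_error(water_balance_step(st0, -1, 0, soil, cfg), ">= 0")
})

test_that("water is conserved to machine tolerance over random sequences", {
  soil <- make_soil(capacity = 80)$soil
  cfg <- growth_config()
  set.seed(99)
  state <- list(paw = 40, runoff_cum = 0, et_cum = 0)
  for (i in 1:300) {
    precip <- stats::rexp(1, 1 / 3) * rbinom(1, 1, 0.4)
    demand <- stats::runif(1, 0, 8)
    prev <- state
    out <- water_balance_step(state, precip, demand, soil, cfg)
    state <- out$state
    runoff <- state$runoff_cum - prev$runoff_cum
    et <- state$et_cum - prev$et_cum
    expect_lt(abs((state$paw - prev$paw) - (precip - runoff - et)), 1e-9)
    expect_true(state$paw >= 0 && state$paw <= soil$paw_capacity)
  }
})

season_inputs <- function(seed = 2, lat = 47) {
  w <- gen_weather(default_archetypes()$continental, 1, seed = seed, lat = lat)
  pl <- decide_planting(w)
  st <- predict_stages(w, pl, "0000", lat = lat)
  list(w = w, st = st)
}

test_that("potential yield bounds rainfed yield and initial water is monotone", {
  si <- season_inputs()
  sl <- make_soil()
  pot <- simulate_season(si$w, si$st, sl$soil, sl$moisture,
                         sim_configuration("potential"))
  ylds <- vapply(c(-1, 0, 1), function(off)
    simulate_season(si$w, si$st, sl$soil, sl$moisture,
                    sim_configuration("rainfed", off))$yield_t_ha, numeric(1))
  expect_true(all(pot$yield_t_ha >= ylds))
  expect_true(all(diff(ylds) >= 0)) # more initial water never hurts
})

test_that("yield is monotone in season precipitation and zero without radiation", {
  si <- season_inputs()
  sl <- make_soil()
  ylds <- vapply(seq(0, 3, length.out = 10), function(f) {
    w <- si$w; w$precip_mm <- w$precip_mm * f
    attr(w, "lat") <- 47
    simulate_season(w, si$st, sl$soil, sl$moisture,
                    sim_configuration("rainfed", 0))$yield_t_ha
  }, numeric(1))
  expect_true(all(diff(ylds) >= -1e-9))

  dark <- si$w; dark$srad_mj_m2 <- 0
  attr(dark, "lat") <- 47
  expect_equal(simulate_season(dark, si$st, sl$soil, sl$moisture,
                               sim_configuration("potential"))$yield_t_ha, 0)
})

test_that("potential-mode yield ignores precipitation and soil inputs", {
  si <- season_inputs()
  a <- simulate_season(si$w, si$st, make_soil(capacity = 50)$soil,
                       make_soil()$moisture, sim_configuration("potential"))
  w2 <- si$w; w2$precip_mm <- 0
  attr(w2, "lat") <- 47
  b <- simulate_season(w2, si$st, make_soil(capacity = 200, sm = 0.4)$soil,
                       make_soil(sm = 0.11)$moisture,
                       sim_configuration("potential"))
  expect_equal(a$yield_t_ha, b$yield_t_ha)
})

test_that("incomplete stages are rejected", {
  si <- season_inputs()
  sl <- make_soil()
  bad <- make_stages(100, 110, 150, 180, NA)
  expect_error(simulate_season(si$w, bad, sl$soil, sl$moisture), "R7")
})
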