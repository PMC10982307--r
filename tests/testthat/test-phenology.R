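test_that("daily GDU follows the clamped-mean rule", {
  expect_equal(daily_gdu(10, 30), 10)
  expect_equal(daily_gdu(5, 35), 10)   # clamping saturates both bounds
  expect_equal(daily_gdu(8, 12), 1)    # (10 + 12)/2 - 10
  expect_equal(daily_gdu(-20, -5), 0)
  expect_error(daily_gdu(12, 8), "tmax")
  # result always within [0, gdu_max - gdu_base]
  set.seed(1)
  tmin <- runif(500, -30, 35)
  tmax <- tmin + runif(500, 0, 25)
  g <- daily_gdu(tmin, tmax)
  expect_true(all(g >= 0 & g <= 20))
})

test_that("the adaptive planting rule honours window, bounds and cutoff", {
  warm <- series_with_gdu(5.0)
  mar1 <- as.integer(strftime(as.Date("2001-03-01"), "%j"))
  expect_equal(decide_planting(warm), mar1) # earliest allowed date

  boundary <- series_with_gdu(4.4)
  expect_true(is.na(decide_planting(boundary))) # strict inequality

  # cold through March, constant 6 GDU from 1 April: first trailing window
  # that clears 4.4 holds six warm days (6*6/7 > 4.4 > 5*6/7)
  apr1 <- as.integer(strftime(as.Date("2001-04-01"), "%j"))
  gdu <- ifelse(seq_len(365) >= apr1, 6, 0)
  step <- make_series(tmin = 10, tmax = 10 + 2 * gdu)
  expect_equal(decide_planting(step), apr1 + 5)

  # warm only after the latest-planting cutoff: never plants
  jul1 <- as.integer(strftime(as.Date("2001-07-01"), "%j"))
  late <- make_series(tmin = 10, tmax = ifelse(seq_len(365) >= jul1, 22, 10))
  expect_true(is.na(decide_planting(late)))

  expect_error(decide_planting(warm[1:3, ]), "window")
})

test_that("stage dates follow hand-computed thermal-time accumulation", {
  cfg <- phenology_config(mg_targets = data.frame(
    mg = "X", r1 = 400, r5 = 700, r7 = 1100, photoperiod_sens = 0))
  s <- series_with_gdu(10)
  st <- predict_stages(s, planting = 100, mg = "X", cfg = cfg)
  expect_equal(st$emergence, 100 + 7)   # 70 GDU at 10/day
  expect_equal(st$r1, st$emergence + 40)
  expect_equal(st$r5, st$emergence + 70)
  expect_equal(st$r7, st$emergence + 110)
  expect_true(st$reached_r7)

  # all-zero GDU after planting: no emergence
  cold <- make_series(tmin = 5, tmax = 9)
  st0 <- predict_stages(cold, planting = 100, mg = "X", cfg = cfg)
  expect_true(is.na(st0$emergence))
  expect_false(st0$reached_r7)

  # at accumulation just above the planting threshold, emergence takes
  # ceil(70/4.4) = 16 days
  slow <- series_with_gdu(4.41)
  st16 <- predict_stages(slow, planting = 100, mg = "X", cfg = cfg)
  expect_equal(st16$emergence - 100, 16)

  expect_error(predict_stages(s, planting = NA, mg = "X", cfg = cfg), "planting")
  expect_error(predict_stages(s, planting = 100, mg = "nope"), "maturity group")
})

test_that("stage ordering and maturity-group monotonicity hold on generated weather", {
  mgs <- default_mg_targets()$mg
  for (seed in 1:5) {
    w <- gen_weather(default_archetypes()$mediterranean, 1, seed = seed,
                     lat = 40)
    pl <- decide_planting(w)
    expect_false(is.na(pl))
    r7s <- rep(NA_integer_, length(mgs))
    for (k in seq_along(mgs)) {
      st <- predict_stages(w, pl, mgs[k], lat = 40)
      if (st$reached_r7) {
        expect_true(st$planting <= st$emergence)
        expect_true(st$emergence < st$r1)
        expect_true(st$r1 < st$r5)
        expect_true(st$r5 < st$r7)
        r7s[k] <- st$r7
      }
    }
    expect_true(all(diff(r7s[!is.na(r7s)]) >= 0)) # later MG never earlier
  }
})

test_that("a uniform +1 degC warming never delays any stage", {
  for (seed in 1:5) {
    w <- gen_weather(default_archetypes()$continental, 1, seed = seed, lat = 47)
    warm <- w
    warm$tmin_c <- w$tmin_c + 1
    warm$tmax_c <- w$tmax_c + 1
    attr(warm, "lat") <- 47
    p0 <- decide_planting(w); p1 <- decide_planting(warm)
    if (is.na(p0)) next
    expect_lte(p1, p0)
    for (mg in c("0000", "00", "II")) {
      s0 <- predict_stages(w, p0, mg, lat = 47)
      s1 <- predict_stages(warm, p1, mg, lat = 47)
      for (f in c("emergence", "r1", "r5", "r7"))
        if (!is.na(s0[[f]])) {
          expect_false(is.na(s1[[f]]))
          expect_lte(s1[[f]], s0[[f]])
        }
    }
  }
})

test_that("daylength behaves like the solar-declination formula", {
  expect_equal(daylength(0, 172), 12, tolerance = 0.01)  # equator
  expect_gt(daylength(60, 172), daylength(40, 172))      # midsummer north
  expect_lt(daylength(60, 355), daylength(40, 355))      # midwinter north
})
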