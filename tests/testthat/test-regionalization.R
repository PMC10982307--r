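rainfed_configs <- c("rainfed-1", "rainfed+0", "rainfed+1")
mgs <- default_mg_targets()$mg

test_that("site summaries average yields and success as defined", {
  # all simulations failed: zero yields, zero success
  fail <- make_results("A", 2001:2005, mgs, c("potential", rainfed_configs),
                       yield = 0, failed = TRUE, planting = NA)
  s <- summarize_site(fail)
  expect_true(all(s[paste0("yield_", mgs)] == 0))
  expect_true(all(s[paste0("success_", mgs)] == 0))
  expect_true(is.na(s$mean_planting_doy))

  # one failing year in twenty gives success 0.95
  ok <- make_results("B", 2001:2020, mgs, rainfed_configs,
                     yield = 3, failed = FALSE)
  ok$failed[ok$year == 2007] <- TRUE
  ok$yield_t_ha[ok$failed] <- 0
  s2 <- summarize_site(ok)
  expect_equal(unname(unlist(s2[paste0("success_", mgs)])), rep(0.95, 7))

  # yields {2,3,4} across the three initial conditions average to 3
  one <- make_results("C", 2001, mgs, rainfed_configs, yield = 0,
                      failed = FALSE)
  one$yield_t_ha <- rep(c(2, 3, 4), each = 7)
  s3 <- summarize_site(one)
  expect_true(all(s3[paste0("yield_", mgs)] == 3))

  expect_error(summarize_site(ok[ok$mg != "III", ]), "maturity groups")
})

test_that("the distance band defines the spatial adjacency", {
  # two sites ~50 km apart are neighbours; ~80 km are not
  g <- data.frame(site_id = c("a", "b", "c"),
                  lat = c(50, 50.45, 50.72), lon = 5)
  adj <- build_spatial_weights(g, band_km = 75)
  expect_true(adj["a", "b"])   # ~50 km
  expect_false(adj["a", "c"])  # ~80 km
  expect_false(any(diag(adj)))
  expect_identical(adj, t(adj))
  # 0.5 degree latitude neighbours (~55.6 km) connect, 1.0 degree does not
  g2 <- data.frame(site_id = c("p", "q", "r"), lat = c(45, 45.5, 46), lon = 0)
  adj2 <- build_spatial_weights(g2, band_km = 75)
  expect_true(adj2["p", "q"])
  expect_false(adj2["p", "r"])
  expect_error(build_spatial_weights(g[1, , drop = FALSE]), "two sites")
})

# A summaries frame with planted per-site values in the 15 statistics.
planted_summaries <- function(grid, centers, noise_sd, seed) {
  set.seed(seed)
  n <- nrow(grid)
  x <- matrix(0, n, 15)
  for (i in seq_len(n))
    x[i, ] <- centers[[grid$truth[i]]] + rnorm(15, 0, noise_sd)
  df <- data.frame(site_id = grid$site_id, x, stringsAsFactors = FALSE)
  names(df) <- c("site_id", paste0("yield_", mgs), paste0("success_", mgs),
                 "mean_planting_doy")
  df
}

test_that("spatially separated identical blocks are recovered exactly", {
  g <- rbind(data.frame(site_id = paste0("n", 1:4), lat = 50 + 0.5 * (0:3), lon = 0),
             data.frame(site_id = paste0("s", 1:4), lat = 40 + 0.5 * (0:3), lon = 0))
  g$truth <- rep(1:2, each = 4)
  centers <- list(rep(1, 15), rep(5, 15))
  sm <- planted_summaries(g, centers, noise_sd = 0, seed = 1)
  adj <- build_spatial_weights(g, 75)
  expect_warning(labels <- cluster_sites(sm, adj, 2), NA)
  expect_equal(adjusted_rand(labels, g$truth), 1)
  expect_identical(labels, cluster_sites(sm, adj, 2)) # deterministic
})

test_that("constrained Ward with full adjacency matches unconstrained Ward", {
  set.seed(42)
  g <- data.frame(site_id = sprintf("s%02d", 1:30),
                  lat = 45 + 0.2 * (0:29), lon = 3)
  sm <- data.frame(site_id = g$site_id,
                   matrix(rnorm(30 * 15), 30, 15))
  names(sm) <- c("site_id", paste0("yield_", mgs), paste0("success_", mgs),
                 "mean_planting_doy")
  full <- matrix(TRUE, 30, 30); diag(full) <- FALSE
  dimnames(full) <- list(g$site_id, g$site_id)
  mine <- cluster_sites(sm, full, 4)
  # independent route: classic Ward via hclust on squared distances of the
  # same min-max normalised data
  x <- as.matrix(sm[, -1])
  x <- sweep(sweep(x, 2, apply(x, 2, min)), 2,
             apply(x, 2, max) - apply(x, 2, min), "/")
  ref <- cutree(hclust(as.dist(as.matrix(dist(x))^2), method = "ward.D"), 4)
  expect_equal(adjusted_rand(mine, ref), 1)
})

test_that("adjusted Rand agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand(1:10, rep(1:5, 2)) ,
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})

test_that("constant variables are dropped with a warning", {
  g <- data.frame(site_id = paste0("s", 1:6), lat = 45 + 0.5 * (0:5), lon = 0,
                  truth = rep(1:2, each = 3))
  centers <- list(c(rep(1, 14), 0), c(rep(4, 14), 0)) # last column constant
  sm <- planted_summaries(g, centers, 0, seed = 1)
  adj <- build_spatial_weights(g, 75)
  expect_warning(labels <- cluster_sites(sm, adj, 2), "constant")
  expect_equal(adjusted_rand(labels, g$truth), 1)
})

test_that("planted three-cluster structure on a grid is recovered", {
  grid <- gen_site_grid(15, 6, 0.5)
  grid$truth <- cut(grid$lat, 3, labels = FALSE)
  adj <- build_spatial_weights(grid, 75)
  centers <- list(c(rep(0.5, 7), rep(0.9, 7), 120),
                  c(rep(2.5, 7), rep(0.5, 7), 140),
                  c(rep(4.5, 7), rep(0.1, 7), 160))
  ari <- vapply(1:5, function(seed) {
    sm <- planted_summaries(grid, centers, noise_sd = 0.25, seed = seed)
    adjusted_rand(cluster_sites(sm, adj, 3), grid$truth)
  }, numeric(1))
  expect_true(all(ari >= 0.9))
})

test_that("extra graph components become their own clusters with a warning", {
  g <- rbind(data.frame(site_id = paste0("a", 1:2), lat = c(50, 50.5), lon = 0),
             data.frame(site_id = paste0("b", 1:2), lat = c(40, 40.5), lon = 0),
             data.frame(site_id = paste0("c", 1:2), lat = c(45, 45.5), lon = 20))
  g$truth <- rep(1:3, each = 2)
  sm <- planted_summaries(g, list(rep(1, 15), rep(2, 15), rep(3, 15)), 0, 1)
  adj <- build_spatial_weights(g, 75)
  expect_warning(labels <- cluster_sites(sm, adj, 2), "components")
  expect_equal(length(unique(labels)), 3)
})

test_that("the cluster summary table reports best-MG statistics per cluster", {
  # two clusters with hand-set yields {3,3,3} and {5,5,5}
  sm <- data.frame(site_id = paste0("s", 1:6),
                   matrix(0, 6, 15), stringsAsFactors = FALSE)
  names(sm) <- c("site_id", paste0("yield_", mgs), paste0("success_", mgs),
                 "mean_planting_doy")
  sm$yield_00 <- c(3, 3, 3, 5, 5, 5)
  sm$success_00 <- 0.9
  sm$mean_planting_doy <- 130
  labels <- rep(1:2, each = 3)
  tab <- cluster_summary_table(labels, sm)
  expect_equal(tab$rainfed_mean, c(3, 5))
  expect_equal(tab$rainfed_sd, c(0, 0))
  expect_equal(tab$mg_rainfed, c("00", "00"))
  expect_equal(tab$success_pct, c(90, 90))

  # a single-cluster degenerate input equals the global summary
  tab1 <- cluster_summary_table(rep(1, 6), sm)
  expect_equal(tab1$rainfed_mean, mean(sm$yield_00))

  # a cluster where everything fails is coded 0 +/- 0, "na"
  smf <- sm; smf[, 2:16] <- 0
  tabf <- cluster_summary_table(rep(1, 6), smf)
  expect_equal(tabf$rainfed_mean, 0)
  expect_equal(tabf$rainfed_sd, 0)
  expect_equal(tabf$mg_rainfed, "na")
  expect_equal(tabf$success_pct, 0)
})
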