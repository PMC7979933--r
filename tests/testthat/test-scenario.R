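# A small fitted world reused across scenario tests: constant negative
# temperature effect, identity-like transform, no noise.
scenario_world <- function(n = 150, seed = 70) {
  grid <- generate_landscape(20, 20, 1000, 4, seed = seed)
  stack <- generate_predictor_fields(grid, c("temperature", "precipitation"),
                                     smoothness = 2, seed = seed + 1)
  nc <- grid$nx * grid$ny
  truth <- synthetic_truth(
    list(intercept = rep(20, nc), temperature = rep(-1, nc),
         precipitation = rep(0.5, nc)),
    lambda = 1, noise_sd = 0)
  gen <- generate_observations(grid, stack, truth, n, seed = seed + 2)
  obs <- gen$observations
  z <- boxcox_apply(obs$stock, 1)
  fit <- suppressMessages(fit_gwr(
    as.matrix(obs[c("temperature", "precipitation")]), z,
    as.matrix(obs[c("x", "y")]), gwr_config(k_range = c(20, n))))
  list(grid = grid, stack = stack, obs = obs, fit = fit,
       bc = list(lambda = 1))
}

test_that("a null scenario reproduces the baseline map cell for cell", {
  sw <- scenario_world()
  base <- project_scenario(sw$fit, sw$stack, transform = sw$bc)
  null_scen <- generate_future_climate(sw$stack, c(2030, 2040), 0, 1)
  proj <- project_scenario(sw$fit, sw$stack, null_scen, 2040, sw$bc)
  expect_equal(proj$values, base$values, tolerance = 1e-12)
})

test_that("warming lowers stocks everywhere when all local temperature coefficients are negative", {
  sw <- scenario_world()
  expect_true(all(sw$fit$local_coefficients[, "temperature"] < 0))
  B <- local_coefficients(sw$fit, cell_coords(sw$grid))
  expect_true(all(B[, "temperature"] < 0))
  scen <- scenario_set(
    2100,
    list("2100" = list(temperature = sw$stack$layers$temperature + 2)),
    sw$grid)
  base <- project_scenario(sw$fit, sw$stack, transform = sw$bc,
                           coefficients = B)
  proj <- project_scenario(sw$fit, sw$stack, scen, 2100, sw$bc,
                           coefficients = B)
  expect_true(all(proj$values <= base$values + 1e-10))

  # monotone drift -> totals monotone non-increasing across decades
  drift <- generate_future_climate(sw$stack, seq(2030, 2080, 10), 0.5, 1)
  ser <- decadal_series(sw$fit, sw$stack, drift, sw$bc)
  expect_true(all(diff(ser$total_pg) <= 1e-12))
})

test_that("missing predictor cells propagate to exactly those cells", {
  sw <- scenario_world()
  stack2 <- sw$stack
  stack2$layers$precipitation[c(17, 203)] <- NA
  proj <- project_scenario(sw$fit, stack2, transform = sw$bc)
  expect_true(all(is.na(proj$values[c(17, 203)])))
  expect_true(all(!is.na(proj$values[-c(17, 203)])))
})

test_that("difference maps equal a brute-force cell loop", {
  grid <- landscape_grid(8, 6, 500, rep(1L, 48))
  set.seed(81)
  a <- stock_map(grid, runif(48, 50, 150), scenario = "a")
  b <- stock_map(grid, runif(48, 50, 150), scenario = "b")
  d <- difference_map(a, b)
  manual <- vapply(1:48, function(i) a$values[i] - b$values[i], numeric(1))
  expect_equal(d$values, manual)
  expect_equal(difference_map(a, a)$values, rep(0, 48))

  u1 <- stock_map(grid, rep(110, 48))
  u2 <- stock_map(grid, rep(100, 48))
  expect_equal(unique(difference_map(u1, u2)$values), 10)

  other <- landscape_grid(8, 6, 400, rep(1L, 48))
  expect_error(difference_map(a, stock_map(other, rep(1, 48))),
               "co-registration")
})

test_that("zonal aggregation respects the Mg-to-Tg unit chain and conserves totals", {
  # 100 x 100 cells of 1000 m = 100 ha each -> exactly 1e6 ha
  grid <- landscape_grid(100, 100, 1000, rep(1L, 1e4))
  m <- stock_map(grid, rep(100, 1e4))
  agg <- aggregate_by_region(m)
  expect_region_df(agg)
  expect_equal(agg$total_tg[agg$region == "total"], 100)  # 1e8 Mg = 100 Tg
  expect_equal(agg$area_ha[agg$region == "total"], 1e6)

  # two equal-area regions with means 10 and 30
  labs <- rep(c(1L, 2L), each = 5000)
  grid2 <- landscape_grid(100, 100, 1000, labs)
  m2 <- stock_map(grid2, ifelse(labs == 1, 10, 30))
  agg2 <- aggregate_by_region(m2)
  expect_equal(agg2$mean_stock_mg_ha[agg2$region == "total"], 20)
  expect_equal(sum(agg2$total_tg[agg2$region != "total"]),
               agg2$total_tg[agg2$region == "total"], tolerance = 1e-6)

  # random map with missing cells vs a per-cell loop oracle
  set.seed(91)
  grid5 <- generate_landscape(20, 20, 800, 5, seed = 14)
  vals <- runif(400, 0, 300)
  vals[sample(400, 25)] <- NA
  m5 <- stock_map(grid5, vals)
  agg5 <- aggregate_by_region(m5)
  for (r in 1:5) {
    v <- vals[grid5$region_labels == r]
    expect_equal(agg5$mean_stock_mg_ha[agg5$region == as.character(r)],
                 mean(v, na.rm = TRUE))
    expect_equal(agg5$total_tg[agg5$region == as.character(r)],
                 sum(v, na.rm = TRUE) * 800^2 / 1e4 * 1e-6)
  }
  expect_equal(sum(agg5$total_tg[agg5$region != "total"]),
               agg5$total_tg[agg5$region == "total"], tolerance = 1e-6)
})

test_that("a single-decade series equals projection plus aggregation", {
  sw <- scenario_world()
  scen <- generate_future_climate(sw$stack, 2050, 0.4, 0.95)
  ser <- decadal_series(sw$fit, sw$stack, scen, sw$bc)
  expect_equal(nrow(ser), 1L)
  m <- project_scenario(sw$fit, sw$stack, scen, 2050, sw$bc)
  agg <- aggregate_by_region(m)
  expect_equal(ser$total_pg, agg$total_tg[agg$region == "total"] * 1e-3)
  expect_equal(ser$mean_mg_ha, mean(m$values))
  expect_equal(ser$min_mg_ha, min(m$values))
})

test_that("comparison against a coarse external grid block-averages correctly", {
  fine <- landscape_grid(8, 8, 500, rep(1L, 64))
  set.seed(17)
  vals <- runif(64, 80, 120)
  ours <- stock_map(fine, vals)
  # 4:1 coarsening: coarse 2x2 grid of 2000 m cells, centres aligned
  coarse <- landscape_grid(2, 2, 2000, rep(1L, 4),
                           origin_x = 750, origin_y = 750)
  # loop oracle for the block means
  xy <- cell_coords(fine)
  block <- numeric(4)
  for (cix in 1:2) for (ciy in 1:2) {
    inx <- xy[, 1] >= (cix - 1) * 2000 - 250 & xy[, 1] < cix * 2000 - 250
    iny <- xy[, 2] >= (ciy - 1) * 2000 - 250 & xy[, 2] < ciy * 2000 - 250
    block[(ciy - 1) * 2 + cix] <- mean(vals[inx & iny])
  }
  ext_self <- stock_map(coarse, block, scenario = "external")
  diff0 <- compare_external_soc(ours, ext_self)
  expect_equal(diff0$values, rep(0, 4), tolerance = 1e-12)

  ext <- stock_map(coarse, rep(100, 4), scenario = "external")
  d <- compare_external_soc(ours, ext)
  expect_equal(d$values, block - 100, tolerance = 1e-12)

  far <- landscape_grid(2, 2, 2000, rep(1L, 4), origin_x = 1e7, origin_y = 1e7)
  expect_error(compare_external_soc(ours, stock_map(far, rep(1, 4))),
               "overlap")
})
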