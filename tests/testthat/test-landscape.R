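test_that("landscape generation gives a deterministic Voronoi partition", {
  one <- generate_landscape(10, 10, 800, 1, seed = 3)
  expect_equal(unique(one$region_labels), 1L)

  a <- generate_landscape(10, 10, 800, 4, seed = 42)
  b <- generate_landscape(10, 10, 800, 4, seed = 42)
  expect_identical(a$region_labels, b$region_labels)

  big <- generate_landscape(60, 60, 800, 5, seed = 7)
  sizes <- table(big$region_labels)
  expect_length(sizes, 5L)
  expect_true(all(sizes > 0))
  expect_equal(sum(sizes), 3600)
  expect_true(patches_contiguous(big))

  expect_error(generate_landscape(0, 10, 800, 1, seed = 1), "counts")
  expect_error(generate_landscape(10, 10, -1, 1, seed = 1), "positive")
  expect_error(generate_landscape(3, 3, 800, 10, seed = 1), "n_regions")
})

test_that("continuous predictor fields are standardized with the requested range of spatial correlation", {
  grid <- landscape_grid(100, 100, 800, rep(1L, 1e4))
  st <- generate_predictor_fields(grid, c("a", "b"), smoothness = 1, seed = 9)
  for (nm in c("a", "b")) {
    v <- st$layers[[nm]]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(var(v) - 1), 1e-9)
  }
  # lag-5 autocorrelation along x for a correlation length of 1 cell ~ 0
  m <- matrix(st$layers$a, nrow = 100, byrow = TRUE)
  r5 <- cor(as.vector(m[, 1:95]), as.vector(m[, 6:100]))
  expect_lt(abs(r5), 0.1)
  # and clearly positive at lag 2 for a correlation length of 4 cells
  st4 <- generate_predictor_fields(grid, "a", smoothness = 4, seed = 9)
  m4 <- matrix(st4$layers$a, nrow = 100, byrow = TRUE)
  expect_gt(cor(as.vector(m4[, 1:98]), as.vector(m4[, 3:100])), 0.5)
})

test_that("categorical layers are one-hot with a dropped reference class", {
  grid <- landscape_grid(20, 20, 800, rep(1L, 400))
  st <- generate_predictor_fields(grid, "temperature", c(soil = 3L),
                                  smoothness = 3, seed = 4)
  expect_setequal(st$indicator, c("soil_2", "soil_3"))
  sums <- st$layers$soil_2 + st$layers$soil_3
  expect_true(all(sums %in% c(0, 1)))
  expect_true(all(st$layers$soil_2 %in% c(0, 1)))
  expect_error(
    generate_predictor_fields(grid, "soil", c(soil = 3L), smoothness = 2),
    "duplicate")
})

test_that("observation sampling honours the truth model exactly in the noiseless identity case", {
  grid <- generate_landscape(15, 15, 800, 2, seed = 1)
  stack <- generate_predictor_fields(grid, c("u", "v"), smoothness = 2,
                                     seed = 2)
  nc <- grid$nx * grid$ny
  truth <- synthetic_truth(
    list(intercept = rep(4, nc), u = rep(2, nc), v = rep(-1, nc)),
    lambda = 1, noise_sd = 0)
  gen <- generate_observations(grid, stack, truth, 50, seed = 3)
  obs <- gen$observations
  # lambda = 1 shifts by 1: y = 1 + z
  expect_equal(obs$stock, 1 + 4 + 2 * obs$u - 1 * obs$v, tolerance = 1e-12)
  # closed-form OLS recovers the constant surfaces
  co <- coef(lm(I(stock - 1) ~ u + v, data = obs))
  expect_equal(unname(co), c(4, 2, -1), tolerance = 1e-8)
  # determinism
  gen2 <- generate_observations(grid, stack, truth, 50, seed = 3)
  expect_identical(gen$observations, gen2$observations)
})

test_that("generated stocks are positive and right-skewed for lambda below one", {
  w <- make_world(nx = 32, ny = 32, n = 600, seed = 11)
  s <- w$obs$stock
  expect_true(all(s > 0))
  skew <- mean(((s - mean(s)) / sd(s))^3)
  expect_gt(skew, 0)
})

test_that("profiles tile the metre and reproduce the target stock through the stock formula", {
  w <- make_world(n = 40, seed = 8)
  prof <- generate_profiles(w$obs, layers_per_profile = 5, seed = 12)
  stocks <- vapply(prof, compute_profile_stock, numeric(1))
  expect_equal(stocks, w$obs$stock, tolerance = 1e-9)
  for (p in prof[1:5]) {
    l <- p$layers
    expect_equal(l$top[1], 0)
    expect_equal(l$bottom[nrow(l)], 100)
    expect_equal(l$top[-1], l$bottom[-nrow(l)])  # no gaps, no overlap
  }
  single <- generate_profiles(w$obs[1, ], 1, seed = 1)[[1]]
  expect_equal(nrow(single$layers), 1L)
  expect_equal(compute_profile_stock(single), w$obs$stock[1])
})

test_that("future-climate overrides follow the prescribed decadal drift", {
  w <- make_world(n = 20, seed = 21)
  decades <- seq(2030, 2100, by = 10)
  null_scen <- generate_future_climate(w$stack, decades, 0, 1, seed = 1)
  expect_equal(null_scen$overrides[["2100"]]$temperature,
               w$stack$layers$temperature)
  expect_equal(null_scen$overrides[["2100"]]$precipitation,
               w$stack$layers$precipitation)

  scen <- generate_future_climate(w$stack, decades, 0.5, 0.97, seed = 1)
  expect_equal(mean(scen$overrides[["2100"]]$temperature) -
                 mean(w$stack$layers$temperature), 4.0, tolerance = 1e-9)
  expect_equal(mean(scen$overrides[["2100"]]$precipitation),
               mean(w$stack$layers$precipitation * 0.97^8), tolerance = 1e-12)

  expect_error(
    generate_future_climate(w$stack, decades, 0.5, 1, temp_name = "absent"),
    "missing layer")
})
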