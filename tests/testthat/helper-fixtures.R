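# Shared fixture builders. Everything is generated in code; no data files.

# Breadth-first check that the cells of each region label form a single
# 4-connected patch — the brute-force contiguity oracle.
patches_contiguous <- function(grid) {
  lab <- matrix(grid$region_labels, nrow = grid$ny, ncol = grid$nx,
                byrow = TRUE)
  for (r in unique(grid$region_labels)) {
    cells <- which(lab == r, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(cells))
    key <- paste(cells[, 1], cells[, 2])
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue)) {
      i <- queue[1L]
      queue <- queue[-1L]
      nb <- rbind(cells[i, ] + c(1, 0), cells[i, ] - c(1, 0),
                  cells[i, ] + c(0, 1), cells[i, ] - c(0, 1))
      j <- match(paste(nb[, 1], nb[, 2]), key)
      j <- j[!is.na(j)]
      j <- j[!seen[j]]
      seen[j] <- TRUE
      queue <- c(queue, j)
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}

# A small synthetic world shared by several tests: rough predictor fields,
# smooth truth surfaces with nonzero mean climate effects.
make_world <- function(nx = 25, ny = 25, n = 220, seed = 42,
                       lambda = 0.1, noise_sd = 0.2, n_regions = 4,
                       coef_sd = 0.3) {
  grid <- generate_landscape(nx, ny, 800, n_regions, seed = seed)
  stack <- generate_predictor_fields(grid, c("temperature", "precipitation"),
                                     smoothness = 2, seed = seed + 1)
  truth <- generate_truth(grid, names(stack$layers), smoothness = 8,
                          intercept_mean = 7, intercept_sd = 0.8,
                          coef_mean = c(temperature = -0.5,
                                        precipitation = 0.4),
                          coef_sd = coef_sd, lambda = lambda,
                          noise_sd = noise_sd, seed = seed + 2)
  gen <- generate_observations(grid, stack, truth, n, seed = seed + 3)
  list(grid = grid, stack = stack, truth = truth,
       obs = gen$observations, held = gen$truth)
}

# A deterministic GWR fit on exactly linear data (noiseless, identity
# transform): every local fit recovers the same global plane.
make_constant_fit <- function(n = 80, seed = 5, kernel = "bisquare",
                              noise_sd = 0) {
  set.seed(seed)
  coords <- cbind(x = runif(n, 0, 1e4), y = runif(n, 0, 1e4))
  X <- cbind(temperature = rnorm(n), precipitation = rnorm(n))
  z <- 10 - 1.5 * X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, noise_sd)
  fit <- suppressMessages(
    fit_gwr(X, z, coords, gwr_config(kernel = kernel, k_range = c(10, n))))
  list(fit = fit, X = X, z = z, coords = coords)
}

expect_region_df <- function(df) {
  expect_true(all(c("region", "n_cells", "mean_stock_mg_ha", "area_ha",
                    "total_tg") %in% names(df)))
}
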