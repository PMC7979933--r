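test_that("kernel weights match their closed forms", {
  expect_equal(kernel_weight(0, 2, "bisquare"), 1)
  expect_equal(kernel_weight(0, 2, "gaussian"), 1)
  expect_equal(kernel_weight(2, 2, "bisquare"), 0)
  expect_equal(kernel_weight(3, 2, "bisquare"), 0)
  expect_equal(kernel_weight(2, 2, "gaussian"), exp(-0.5))
  expect_equal(kernel_weight(1, 2, "bisquare"), (1 - 0.25)^2)
  expect_error(kernel_weight(1, 0, "bisquare"), "positive")
  expect_error(kernel_weight(-1, 2, "gaussian"), "non-negative")
})

test_that("adaptive bandwidth is the k-th neighbour distance with a coincidence floor", {
  coords <- cbind(c(0, 1, 2, 3), 0)
  expect_equal(adaptive_bandwidth(c(0, 0), coords, 3), 2)
  expect_equal(adaptive_bandwidth(c(0, 0), coords, 4), 3)
  # query on a calibration point with k = 1: floored, never zero
  b <- adaptive_bandwidth(c(1, 0), coords, 1)
  expect_gt(b, 0)
  expect_lt(b, 1e-6)
  expect_error(adaptive_bandwidth(c(0, 0), coords[0, , drop = FALSE], 1),
               "empty")
  expect_error(adaptive_bandwidth(c(0, 0), coords, 9), "k must be")
})

test_that("local weighted fits agree with independent dense solves", {
  set.seed(20)
  n <- 40
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  colnames(X) <- c("(Intercept)", "a", "b")
  z <- X %*% c(2, -1, 0.5) + rnorm(n, 0, 0.2)

  # uniform weights reduce to OLS
  fl <- fit_local(X, z, rep(1, n), focal = 1)
  ols <- lm.fit(X, z)
  expect_equal(unname(fl$beta), unname(coef(ols)), tolerance = 1e-8)

  # random weights vs a brute-force normal-equation solve
  for (i in 1:10) {
    w <- runif(n)
    fl <- fit_local(X, z, w, focal = 3)
    W <- diag(w)
    beta_brute <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)
    expect_equal(unname(fl$beta), unname(drop(beta_brute)), tolerance = 1e-8)
    S <- X %*% solve(t(X) %*% W %*% X) %*% t(X) %*% W
    expect_equal(fl$hat, S[3, 3], tolerance = 1e-8)
  }

  # weights concentrated on exactly p points interpolate them
  w3 <- rep(0, n); w3[c(2, 7, 19)] <- 1
  fl3 <- fit_local(X, z, w3)
  expect_equal(drop(X[c(2, 7, 19), ] %*% fl3$beta), z[c(2, 7, 19)],
               tolerance = 1e-8)

  expect_error(fit_local(X, z, c(1, 1, rep(0, n - 2))), "fewer")
})

test_that("corrected AIC follows its closed form", {
  expect_equal(compute_aicc(100, 10, 1), 100 * log(2 * pi) + 100 * 110 / 88)
  a1 <- compute_aicc(50, 5, 0.7)
  expect_equal(compute_aicc(50, 5, 1.4) - a1, 2 * 50 * log(2))
  # reduces to the OLS AICc when trace_S is the OLS hat trace
  set.seed(2)
  n <- 60
  X <- cbind(1, rnorm(n))
  z <- X %*% c(1, 2) + rnorm(n)
  ols <- lm.fit(X, z)
  sigma <- sqrt(sum(ols$residuals^2) / n)
  expect_equal(compute_aicc(n, 2, sigma),
               2 * n * log(sigma) + n * log(2 * pi) + n * (n + 2) / (n - 4))
  expect_error(compute_aicc(10, 9, 1), "oversmoothing")
})

test_that("bandwidth selection tracks the spatial structure of the coefficients", {
  cf <- make_constant_fit(n = 100, seed = 3, noise_sd = 0.5)
  # globally constant coefficients: AICc keeps improving with neighbours
  expect_gte(cf$fit$k_selected, 0.9 * 100)

  w <- make_world(nx = 30, ny = 30, n = 250, seed = 60, noise_sd = 0.05,
                  coef_sd = 0.6)
  z <- boxcox_apply(w$obs$stock, w$truth$lambda)
  k_het <- suppressMessages(select_bandwidth(
    as.matrix(w$obs[c("temperature", "precipitation")]), z,
    as.matrix(w$obs[c("x", "y")])))
  expect_lt(k_het, 250 / 4)

  # degenerate range returns without search
  k_fix <- select_bandwidth(cf$X, cf$z, cf$coords,
                            gwr_config(k_range = c(30, 30)))
  expect_equal(as.integer(k_fix), 30L)
})

test_that("GWR matches OLS in the wide-bandwidth gaussian limit and interpolates exactly linear data", {
  cf <- make_constant_fit(n = 70, seed = 9)
  diam <- sqrt(2) * 1e4
  fit_wide <- fit_gwr(cf$X, cf$z, cf$coords,
                      gwr_config(kernel = "gaussian",
                                 fixed_bandwidth = 1e6 * diam))
  ols <- lm(cf$z ~ cf$X)
  for (i in c(1, 35, 70)) {
    expect_equal(unname(fit_wide$local_coefficients[i, ]),
                 unname(coef(ols)), tolerance = 1e-6)
  }
  expect_equal(fit_wide$fitted, unname(fitted(ols)), tolerance = 1e-6)

  # noiseless linear data: every local fit finds the exact plane
  expect_lt(max(abs(sweep(cf$fit$local_coefficients, 2,
                          c(10, -1.5, 0.5)))), 1e-6)
  expect_true(cf$fit$trace_S >= 3 - 1e-8)
  expect_true(cf$fit$trace_S <= 70 + 1e-8)
})

test_that("predictions are consistent at calibration points and invariant to row order", {
  w <- make_world(n = 120, seed = 33)
  z <- boxcox_apply(w$obs$stock, w$truth$lambda)
  X <- as.matrix(w$obs[c("temperature", "precipitation")])
  coords <- as.matrix(w$obs[c("x", "y")])
  fit <- suppressMessages(fit_gwr(X, z, coords,
                                  gwr_config(k_range = c(20, 120))))
  # coincident point, same predictors -> the calibration fitted value
  zp <- predict_gwr(fit, X[5, , drop = FALSE], coords[5, , drop = FALSE])
  expect_equal(unname(zp), fit$fitted[5], tolerance = 1e-10)

  # constant response -> constant back-transformed prediction
  fitc <- suppressMessages(
    fit_gwr(X, rep(4, nrow(X)), coords, gwr_config(k_range = c(20, 120))))
  pc <- predict_gwr(fitc, X[1:7, ], coords[1:7, ],
                    transform = list(lambda = 1))
  expect_equal(unname(pc), rep(5, 7), tolerance = 1e-8)

  # reordering calibration rows leaves predictions unchanged
  ord <- sample(nrow(X))
  fit2 <- suppressMessages(fit_gwr(X[ord, ], z[ord], coords[ord, ],
                                   gwr_config(k_range = c(20, 120))))
  new_xy <- cbind(x = c(3000, 12000), y = c(4000, 9000))
  new_X <- X[c(2, 9), ]
  expect_equal(predict_gwr(fit, new_X, new_xy),
               predict_gwr(fit2, new_X, new_xy), tolerance = 1e-8)
})

test_that("every local coefficient matches a dense weighted least-squares oracle", {
  for (s in 1:4) {
    set.seed(s)
    n <- 50
    coords <- cbind(runif(n), runif(n))
    X <- cbind(a = rnorm(n), b = rnorm(n))
    z <- 1 + X %*% c(2, -1) + rnorm(n, 0, 0.3)
    fit <- suppressMessages(
      fit_gwr(X, z, coords, gwr_config(k_range = c(15, n))))
    Xd <- cbind(1, X)
    for (i in c(1, 17, 50)) {
      d <- sqrt(colSums((t(coords) - coords[i, ])^2))
      b <- sort(d)[fit$k_selected]
      wgt <- kernel_weight(d, b, "bisquare")
      W <- diag(wgt)
      beta <- solve(t(Xd) %*% W %*% Xd, t(Xd) %*% W %*% z)
      expect_equal(unname(fit$local_coefficients[i, ]), unname(drop(beta)),
                   tolerance = 1e-8)
    }
  }
})
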