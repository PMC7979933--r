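#' GWR configuration
#'
#' @param kernel Spatial weighting kernel: `"bisquare"` (compact support,
#'   the default for adaptive bandwidths) or `"gaussian"`.
#' @param k_range Integer search range `c(k_min, k_max)` for the adaptive
#'   neighbour count; defaults at fit time to
#'   `c(max(p + 3, 10), n_calibration)`.
#' @param fixed_bandwidth Optional fixed bandwidth distance; when given,
#'   adaptive selection is skipped and every local fit uses this support.
#' @param ridge_jitter Non-negative scalar added to the local
#'   normal-equation diagonal when a local system is singular.
#' @param lonlat If `TRUE`, coordinates are lon/lat degrees and distances
#'   are haversine great-circle metres; otherwise planar Euclidean.
#' @return An object of class `gwr_config`.
#' @export
gwr_config <- function(kernel = c("bisquare", "gaussian"), k_range = NULL,
                       fixed_bandwidth = NULL, ridge_jitter = 1e-8,
                       lonlat = FALSE) {
  kernel <- match.arg(kernel)
  if (!is.null(k_range)) {
    if (length(k_range) != 2L || k_range[1L] > k_range[2L]) {
      stop_invalid("k_range must be c(k_min, k_max) with k_min <= k_max")
    }
  }
  if (!is.null(fixed_bandwidth) && fixed_bandwidth <= 0) {
    stop_invalid("fixed_bandwidth must be positive")
  }
  if (ridge_jitter < 0) stop_invalid("ridge_jitter must be non-negative")
  structure(list(kernel = kernel, k_range = k_range,
                 fixed_bandwidth = fixed_bandwidth,
                 ridge_jitter = ridge_jitter, lonlat = lonlat),
            class = "gwr_config")
}

#' Spatial kernel weight
#'
#' Bisquare: `(1 - (d/b)^2)^2` for `d < b`, else 0.
#' Gaussian: `exp(-0.5 (d/b)^2)`.
#'
#' @param d Non-negative distance(s).
#' @param b Bandwidth distance (positive).
#' @param kernel `"bisquare"` or `"gaussian"`.
#' @return Weight(s) in `[0, 1]`.
#' @export
kernel_weight <- function(d, b, kernel = c("bisquare", "gaussian")) {
  kernel <- match.arg(kernel)
  if (b <= 0) stop_invalid("bandwidth must be positive")
  if (any(d < 0)) stop_invalid("distances must be non-negative")
  u <- d / b
  if (kernel == "bisquare") ifelse(u < 1, (1 - u^2)^2, 0) else exp(-0.5 * u^2)
}

#' Adaptive nearest-neighbour bandwidth
#'
#' The bandwidth at a point is the distance to its k-th nearest
#' calibration point (the point itself counts when it is one), so the
#' kernel support shrinks where data are dense. A coincident-point guard
#' floors the bandwidth at `1e-9` times the calibration domain diagonal so
#' a zero bandwidth can never arise.
#'
#' @param point Length-2 coordinate vector.
#' @param calibration_coords Two-column coordinate matrix.
#' @param k Neighbour count (at most the number of calibration points).
#' @param lonlat Use haversine distances.
#' @return Bandwidth distance.
#' @export
adaptive_bandwidth <- function(point, calibration_coords, k, lonlat = FALSE) {
  n <- nrow(calibration_coords)
  if (is.null(n) || n == 0L) stop_invalid("empty calibration set")
  if (!is_count(k) || k > n) stop_invalid("k must be a count <= n_calibration")
  d <- point_distances(point, calibration_coords, lonlat)
  bandwidth_floor(sort(d, partial = k)[k],
                  domain_diagonal(calibration_coords, lonlat))
}

bandwidth_floor <- function(b, diag) max(b, 1e-9 * diag)

#' Local weighted least squares at one focal point
#'
#' Solves the weighted normal equations
#' `beta = (X' W X)^{-1} X' W z` for one calibration or prediction point.
#' On a singular system, `ridge_jitter` is added to the normal-equation
#' diagonal (and noted via a message); with a zero jitter the singularity
#' is an error naming the focal point.
#'
#' @param X Design matrix including the intercept column.
#' @param z Response vector on the transformed scale.
#' @param weights Non-negative kernel weights, at least `ncol(X)` of them
#'   positive.
#' @param ridge_jitter See [gwr_config()].
#' @param focal Optional row index of the focal calibration point; when
#'   given, the returned `hat` is that point's leverage
#'   `S_ii = x_i' (X'WX)^{-1} x_i w_i`.
#' @param quiet Suppress the per-call singularity message (callers that
#'   fit many local models log an aggregate count instead).
#' @return List with `beta` (named coefficient vector), `hat`
#'   (`NA` unless `focal` is given) and `ridged` (whether the jitter was
#'   needed).
#' @export
fit_local <- function(X, z, weights, ridge_jitter = 0, focal = NULL,
                      quiet = FALSE) {
  p <- ncol(X)
  if (sum(weights > 0) < p) {
    stop_invalid("fewer positively weighted points (", sum(weights > 0),
                 ") than parameters (", p, ")")
  }
  Xw <- X * weights
  A <- crossprod(Xw, X)
  bvec <- crossprod(Xw, z)
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  ridged <- is.null(beta)
  if (ridged) {
    if (ridge_jitter <= 0) {
      stop_invalid("singular local fit",
                   if (!is.null(focal)) paste0(" at point ", focal) else "")
    }
    if (!quiet) {
      message("singular local system; applying ridge jitter ", ridge_jitter)
    }
    A <- A + diag(ridge_jitter, p)
    beta <- solve(A, bvec)
  }
  hat <- NA_real_
  if (!is.null(focal)) {
    hat <- drop(crossprod(X[focal, ], solve(A, X[focal, ] * weights[focal])))
  }
  list(beta = setNames(drop(beta), colnames(X)), hat = hat, ridged = ridged)
}

#' Corrected AIC for a GWR fit
#'
#' `AICc = 2 n log(sigma_hat) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))`
#' with `sigma_hat^2 = RSS / n` on the transformed scale and `tr(S)` the
#' hat-matrix trace acting as effective parameter count. The small-sample
#' penalty diverges as `tr(S)` approaches `n - 2`, which is what penalizes
#' undersmoothed (too-local) bandwidths.
#'
#' @param n Calibration size.
#' @param trace_S Hat-matrix trace.
#' @param sigma_hat Residual standard deviation estimate.
#' @return The AICc value.
#' @export
compute_aicc <- function(n, trace_S, sigma_hat) {
  if (n - 2 - trace_S <= 0) {
    stop_invalid("oversmoothing violation: n - 2 - trace_S <= 0 ",
                 "(bandwidth too small)")
  }
  2 * n * log(sigma_hat) + n * log(2 * pi) +
    n * (n + trace_S) / (n - 2 - trace_S)
}

# One full leave-in GWR pass at neighbour count k (or fixed bandwidth b),
# given a precomputed distance matrix. Returns coefficients, per-point
# bandwidths, leverages, fitted values and AICc ingredients.
gwr_pass <- function(Xd, z, D, k = NULL, b_fixed = NULL, kernel, ridge, diag_len) {
  n <- nrow(Xd)
  p <- ncol(Xd)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(Xd)))
  hat <- numeric(n)
  bw <- numeric(n)
  n_ridged <- 0L
  for (i in seq_len(n)) {
    b <- if (is.null(b_fixed)) {
      bandwidth_floor(sort(D[i, ], partial = k)[k], diag_len)
    } else b_fixed
    w <- kernel_weight(D[i, ], b, kernel)
    fl <- fit_local(Xd, z, w, ridge_jitter = ridge, focal = i, quiet = TRUE)
    beta[i, ] <- fl$beta
    hat[i] <- fl$hat
    bw[i] <- b
    n_ridged <- n_ridged + fl$ridged
  }
  if (n_ridged > 0L) {
    message(n_ridged, " singular local system(s) stabilized with ridge ",
            "jitter ", ridge)
  }
  fitted <- rowSums(Xd * beta)
  rss <- sum((z - fitted)^2)
  trace_S <- sum(hat)
  sigma_hat <- sqrt(rss / n)
  list(beta = beta, hat = hat, bandwidths = bw, fitted = fitted,
       residuals = z - fitted, rss = rss, trace_S = trace_S,
       sigma_hat = sigma_hat,
       aicc = compute_aicc(n, trace_S, sigma_hat))
}

#' Select the adaptive bandwidth by AICc minimization
#'
#' Golden-section search over the integer neighbour counts in
#' `config$k_range`, evaluating a full leave-in GWR pass per candidate
#' (memoized), then returning the candidate with the lowest AICc among all
#' evaluated; ties go to the smaller k. Candidates whose hat-matrix trace
#' violates `n - 2 - tr(S) > 0` count as infinitely bad; if every
#' candidate does, the search fails with an error.
#'
#' @param X Predictor matrix (no intercept column).
#' @param z Transformed response.
#' @param coords Two-column calibration coordinates.
#' @param config A [gwr_config()].
#' @return Selected integer k, with the evaluated `(k, AICc)` profile in
#'   attribute `"profile"`.
#' @export
select_bandwidth <- function(X, z, coords, config = gwr_config()) {
  prep <- gwr_prepare(X, z, coords, config)
  k <- select_bandwidth_impl(prep)
  k
}

gwr_prepare <- function(X, z, coords, config) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- nrow(X)
  p <- ncol(X) + 1L
  if (n != length(z) || n != nrow(coords)) {
    stop_invalid("X, z and coords must be co-indexed")
  }
  if (n <= p + 2L) stop_invalid("need n > p + 2 calibration points")
  k_range <- config$k_range %||% c(max(p + 3L, 10L), n)
  k_range <- as.integer(pmin(pmax(k_range, p + 2L), n))
  Xd <- cbind(`(Intercept)` = 1, X)
  list(Xd = Xd, z = z, coords = coords, n = n, p = p,
       D = distance_matrix(coords, config$lonlat),
       diag_len = domain_diagonal(coords, config$lonlat),
       k_range = k_range, config = config)
}

select_bandwidth_impl <- function(prep) {
  cache <- new.env(parent = emptyenv())
  fk <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- tryCatch(
      suppressMessages(
        gwr_pass(prep$Xd, prep$z, prep$D, k = k, kernel = prep$config$kernel,
                 ridge = prep$config$ridge_jitter,
                 diag_len = prep$diag_len)$aicc),
      error = function(e) Inf)
    cache[[key]] <- v
    v
  }
  lo <- prep$k_range[1L]
  hi <- prep$k_range[2L]
  gr <- (sqrt(5) - 1) / 2
  while (hi - lo > 3L) {
    x1 <- hi - floor(gr * (hi - lo))
    x2 <- lo + floor(gr * (hi - lo))
    if (x1 == x2) x1 <- x1 - 1L
    if (fk(x1) <= fk(x2)) hi <- x2 else lo <- x1
  }
  for (k in lo:hi) fk(k)
  ks <- sort(as.integer(ls(cache)))
  vals <- vapply(as.character(ks), function(key) cache[[key]], numeric(1L))
  if (all(!is.finite(vals))) {
    stop_invalid("bandwidth search failed: every candidate k violates ",
                 "n - 2 - trace_S > 0")
  }
  best <- ks[which.min(vals)]  # which.min takes the first (smallest k) on ties
  structure(best, profile = data.frame(k = ks, aicc = vals, row.names = NULL))
}

#' Fit a geographically weighted regression
#'
#' Runs adaptive bandwidth selection (unless `config$fixed_bandwidth` is
#' set), then one local weighted least-squares fit per calibration point.
#' The result carries the local coefficient field, residuals on the
#' transformed scale, the hat-matrix trace, the residual scale estimate
#' and the AICc, plus everything needed to predict at new locations.
#'
#' @param X Predictor matrix or data frame, one column per predictor
#'   (no intercept column — it is added internally).
#' @param z Transformed response at the calibration points.
#' @param coords Two-column coordinate matrix of the calibration points.
#' @param config A [gwr_config()].
#' @return An object of class `gwr_fit`.
#' @export
fit_gwr <- function(X, z, coords, config = gwr_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  prep <- gwr_prepare(X, z, coords, config)
  if (is.null(config$fixed_bandwidth)) {
    k <- select_bandwidth_impl(prep)
    pass <- gwr_pass(prep$Xd, z, prep$D, k = as.integer(k),
                     kernel = config$kernel, ridge = config$ridge_jitter,
                     diag_len = prep$diag_len)
    profile <- attr(k, "profile")
    k <- as.integer(k)
  } else {
    pass <- gwr_pass(prep$Xd, z, prep$D, b_fixed = config$fixed_bandwidth,
                     kernel = config$kernel, ridge = config$ridge_jitter,
                     diag_len = prep$diag_len)
    k <- NA_integer_
    profile <- NULL
  }
  structure(list(
    predictor_names = colnames(X),
    coords = prep$coords, X = X, z = z,
    local_coefficients = pass$beta,
    k_selected = k, bandwidths = pass$bandwidths,
    fitted = pass$fitted, residuals = pass$residuals,
    trace_S = pass$trace_S, sigma_hat = pass$sigma_hat, aicc = pass$aicc,
    aicc_profile = profile, config = config,
    diag_len = prep$diag_len
  ), class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  n <- nrow(x$coords)
  cat("Geographically weighted regression fit\n")
  cat(sprintf("  %d calibration points, %d predictor(s): %s\n",
              n, length(x$predictor_names),
              paste(x$predictor_names, collapse = ", ")))
  if (is.na(x$k_selected)) {
    cat(sprintf("  fixed bandwidth %g (%s kernel)\n",
                x$config$fixed_bandwidth, x$config$kernel))
  } else {
    cat(sprintf("  adaptive bandwidth: k = %d neighbours (%s kernel, AICc-selected)\n",
                x$k_selected, x$config$kernel))
  }
  cat(sprintf("  trace(S) = %.2f, sigma_hat = %.4f, AICc = %.2f\n",
              x$trace_S, x$sigma_hat, x$aicc))
  invisible(x)
}

#' Local coefficients at arbitrary locations
#'
#' Refits the local regression centred at each new location against the
#' calibration data, using the fit's kernel and selected bandwidth rule.
#' This is the coefficient field evaluated off-calibration; scenario
#' projection holds it fixed while predictor values change.
#'
#' @param fit A [gwr_fit()].
#' @param new_coords Two-column coordinate matrix.
#' @return Matrix with one row per new location and one column per
#'   coefficient (intercept first).
#' @export
local_coefficients <- function(fit, new_coords) {
  new_coords <- as.matrix(new_coords)
  Xd <- cbind(`(Intercept)` = 1, fit$X)
  m <- nrow(new_coords)
  out <- matrix(NA_real_, m, ncol(Xd), dimnames = list(NULL, colnames(Xd)))
  lonlat <- fit$config$lonlat
  for (j in seq_len(m)) {
    d <- point_distances(new_coords[j, ], fit$coords, lonlat)
    b <- if (is.null(fit$config$fixed_bandwidth)) {
      bandwidth_floor(sort(d, partial = fit$k_selected)[fit$k_selected],
                      fit$diag_len)
    } else fit$config$fixed_bandwidth
    w <- kernel_weight(d, b, fit$config$kernel)
    out[j, ] <- fit_local(Xd, fit$z, w, ridge_jitter = fit$config$ridge_jitter,
                          quiet = TRUE)$beta
  }
  out
}

#' Predict SOC stocks at new locations
#'
#' Evaluates the local coefficient field at each new location and applies
#' it to the supplied predictor values on the transformed scale; when a
#' Box-Cox transform is given, predictions are back-transformed to Mg/ha,
#' with values outside the inverse's domain emitted as `NA` and their
#' count reported via a message.
#'
#' @param fit A [gwr_fit()].
#' @param new_X Predictor matrix whose columns match
#'   `fit$predictor_names`.
#' @param new_coords Two-column coordinate matrix co-indexed with `new_X`.
#' @param transform Optional [fit_boxcox()] result (or any list with a
#'   `lambda`); `NULL` returns transformed-scale predictions.
#' @return Numeric vector of predictions.
#' @export
predict_gwr <- function(fit, new_X, new_coords, transform = NULL) {
  new_X <- as.matrix(new_X)
  if (ncol(new_X) != length(fit$predictor_names)) {
    stop_invalid("new_X must have one column per fitted predictor")
  }
  if (!is.null(colnames(new_X)) &&
      !identical(colnames(new_X), fit$predictor_names)) {
    if (!all(fit$predictor_names %in% colnames(new_X))) {
      stop_invalid("new_X columns must match the fitted predictors: ",
                   paste(fit$predictor_names, collapse = ", "))
    }
    new_X <- new_X[, fit$predictor_names, drop = FALSE]
  }
  if (nrow(new_X) != nrow(as.matrix(new_coords))) {
    stop_invalid("new_X and new_coords must be co-indexed")
  }
  B <- local_coefficients(fit, new_coords)
  z <- B[, 1L] + rowSums(B[, -1L, drop = FALSE] * new_X)
  if (is.null(transform)) return(z)
  y <- boxcox_invert(z, transform$lambda, missing_on_domain = TRUE)
  n_bad <- sum(is.na(y) & !is.na(z))
  if (n_bad > 0L) {
    message(n_bad, " prediction(s) outside the Box-Cox inverse domain ",
            "emitted as missing")
  }
  y
}
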