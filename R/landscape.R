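#' Generate a synthetic ecoregion landscape
#'
#' Partitions a regular grid into `n_regions` contiguous patches by the
#' nearest-seed (Voronoi) rule: seed cells are drawn uniformly without
#' replacement and every cell takes the label of its nearest seed
#' (Euclidean distance between cell centres, ties to the lowest seed
#' index). The patches stand in for ecoregions as the grouping unit for
#' outlier filtering, residual diagnostics and coefficient PCA.
#'
#' @param nx,ny Grid dimensions in cells.
#' @param cell_size Cell edge in metres (the study's grids are 800 m).
#' @param n_regions Number of ecoregion patches (each is guaranteed
#'   non-empty because a seed cell is always nearest to itself).
#' @param seed Integer RNG seed; the result is reproducible given it.
#' @return A [landscape_grid()] with labels `1:n_regions`.
#' @export
generate_landscape <- function(nx, ny, cell_size, n_regions, seed) {
  if (!is_count(nx, 2L) || !is_count(ny, 2L) || cell_size <= 0) {
    stop_invalid("nx, ny must be counts >= 2 and cell_size positive")
  }
  if (!is_count(n_regions) || n_regions > nx * ny) {
    stop_invalid("n_regions must be a count no larger than nx * ny")
  }
  grid <- landscape_grid(nx, ny, cell_size, rep(1L, nx * ny))
  xy <- cell_coords(grid)
  labels <- with_seed(seed, {
    seeds <- sample(nrow(xy), n_regions)
    d2 <- outer(xy[, 1L], xy[seeds, 1L], "-")^2 +
      outer(xy[, 2L], xy[seeds, 2L], "-")^2
    max.col(-d2, ties.method = "first")
  })
  grid$region_labels <- as.integer(labels)
  grid
}

#' Construct a predictor stack
#'
#' Named, co-registered grid layers on a common [landscape_grid()]. Layer
#' values are numeric vectors in grid cell order; indicator (0/1) layers
#' produced from categorical classes are flagged so the screening stage can
#' exempt them from Pearson pruning.
#'
#' @param grid A [landscape_grid()].
#' @param layers Named list of numeric vectors, one value per cell.
#' @param indicator Character vector naming the 0/1 indicator layers.
#' @param categorical Named list mapping each categorical variable to its
#'   emitted indicator layer names (reference class dropped).
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(grid, layers, indicator = character(),
                            categorical = list()) {
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
    stop_invalid("layers must have unique non-empty names")
  }
  nc <- n_cells(grid)
  ok <- vapply(layers, function(v) is.numeric(v) && length(v) == nc, TRUE)
  if (!all(ok)) stop_invalid("every layer must be numeric with one value per cell")
  structure(list(grid = grid, layers = layers,
                 indicator = indicator, categorical = categorical),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layer(s) on a %d x %d grid (%d indicators)\n",
              length(x$layers), x$grid$nx, x$grid$ny, length(x$indicator)))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Generate smooth synthetic predictor fields
#'
#' Continuous layers are white Gaussian noise convolved with an isotropic
#' Gaussian kernel (standard deviation `smoothness` cells) and then
#' standardized to mean 0, variance 1 over the grid — the statistical
#' structure (smooth spatial fields) the regression stages assume, without
#' mimicking any particular real data source. Each categorical variable is
#' produced by quantile-thresholding an independent smooth field into
#' `n_classes` equal-frequency bands, emitted as `n_classes - 1` one-hot
#' indicator layers with the first band as dropped reference class.
#'
#' @param grid A [landscape_grid()].
#' @param continuous_names Character vector of continuous layer names
#'   (e.g. `c("temperature", "precipitation", "ndvi")`).
#' @param categorical_specs Named integer vector mapping a categorical
#'   variable name to its class count, e.g. `c(soil_order = 4)`.
#' @param smoothness Kernel correlation length in cells (>= 1).
#' @param seed Integer RNG seed.
#' @return A [predictor_stack()].
#' @export
generate_predictor_fields <- function(grid, continuous_names,
                                      categorical_specs = integer(),
                                      smoothness = 10, seed = 1L) {
  if (smoothness < 1) stop_invalid("smoothness must be at least 1 cell")
  cat_names <- names(categorical_specs) %||% character()
  all_names <- c(continuous_names, cat_names)
  if (anyDuplicated(all_names)) stop_invalid("duplicate layer names")
  with_seed(seed, {
    layers <- list()
    indicator <- character()
    categorical <- list()
    for (nm in continuous_names) layers[[nm]] <- smooth_field(grid, smoothness)
    for (nm in cat_names) {
      k <- as.integer(categorical_specs[[nm]])
      if (k < 2L) stop_invalid("categorical layers need at least 2 classes")
      f <- smooth_field(grid, smoothness)
      cuts <- quantile(f, probs = seq_len(k - 1L) / k, type = 7)
      cls <- findInterval(f, cuts) + 1L  # classes 1..k
      made <- character()
      for (j in 2:k) {
        lname <- paste0(nm, "_", j)
        layers[[lname]] <- as.numeric(cls == j)
        made <- c(made, lname)
      }
      indicator <- c(indicator, made)
      categorical[[nm]] <- made
    }
    predictor_stack(grid, layers, indicator, categorical)
  })
}

#' Define the synthetic ground truth of a landscape
#'
#' Holds the spatially varying regression coefficient surface for the
#' intercept and each predictor, the Box-Cox exponent of the response, and
#' the additive noise level on the transformed scale. Downstream recovery
#' tests compare fitted local GWR coefficients against these surfaces.
#'
#' @param surfaces Named list of numeric vectors in grid cell order; must
#'   contain `"intercept"` plus one entry per predictor.
#' @param lambda Box-Cox exponent of the response (`y = invBC(z; lambda)`).
#' @param noise_sd Standard deviation of Gaussian noise added to the
#'   transformed response; must be non-negative.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(surfaces, lambda, noise_sd) {
  if (!"intercept" %in% names(surfaces)) {
    stop_invalid("surfaces must include an 'intercept' entry")
  }
  if (any(!vapply(surfaces, function(s) all(is.finite(s)), TRUE))) {
    stop_invalid("coefficient surfaces must be finite everywhere")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  structure(list(surfaces = surfaces, lambda = lambda, noise_sd = noise_sd),
            class = "synthetic_truth")
}

#' Generate smooth spatially varying coefficient surfaces
#'
#' Convenience generator for [synthetic_truth()]: each surface is an
#' independent smooth standardized field rescaled to `mean + sd * field`.
#'
#' @param grid A [landscape_grid()].
#' @param predictor_names Predictors needing a coefficient surface.
#' @param smoothness Correlation length of the surfaces in cells.
#' @param intercept_mean,intercept_sd Location and spatial spread of the
#'   intercept surface (transformed-response units).
#' @param coef_mean,coef_sd Location and spread of every predictor surface;
#'   either a single value recycled, or a named vector — predictors not
#'   named fall back to mean 0 / sd 1.
#' @param lambda,noise_sd Passed through to [synthetic_truth()].
#' @param seed Integer RNG seed.
#' @export
generate_truth <- function(grid, predictor_names, smoothness = 15,
                           intercept_mean = 7, intercept_sd = 0.8,
                           coef_mean = 0, coef_sd = 1,
                           lambda = 0.1, noise_sd = 0.3, seed = 1L) {
  expand <- function(v, fill) {
    if (is.null(names(v))) return(rep_len(v, length(predictor_names)))
    out <- rep_len(fill, length(predictor_names))
    names(out) <- predictor_names
    hit <- intersect(names(v), predictor_names)
    out[hit] <- v[hit]
    unname(out)
  }
  cm <- expand(coef_mean, 0)
  cs <- expand(coef_sd, 1)
  with_seed(seed, {
    surfaces <- list(intercept = intercept_mean +
                       intercept_sd * smooth_field(grid, smoothness))
    for (i in seq_along(predictor_names)) {
      surfaces[[predictor_names[i]]] <-
        cm[i] + cs[i] * smooth_field(grid, smoothness)
    }
    synthetic_truth(surfaces, lambda, noise_sd)
  })
}

#' Sample synthetic SOC observations from a landscape
#'
#' Draws `n` distinct cells uniformly, builds the transformed response
#' `z_i = b0(s_i) + sum_k b_k(s_i) x_k(s_i) + eps_i` from the truth
#' surfaces, and reports the stock `y_i` through the inverse Box-Cox
#' transform, which is strictly positive wherever defined. Rows whose
#' noise draw lands outside the inverse's domain (`lambda * z + 1 <= 0`)
#' are re-drawn up to 100 times before failing.
#'
#' @param grid A [landscape_grid()].
#' @param stack A [predictor_stack()] on the same grid.
#' @param truth A [synthetic_truth()] covering every stack layer.
#' @param n Number of observations (at most the number of cells).
#' @param seed Integer RNG seed.
#' @return A list with `observations` (data frame: `id`, `cell`, `x`, `y`,
#'   `region`, `stock`, one column per predictor) and `truth` (the held-out
#'   per-row record: true local coefficients and noiseless/noisy
#'   transformed response).
#' @export
generate_observations <- function(grid, stack, truth, n, seed) {
  if (!is_count(n) || n > n_cells(grid)) {
    stop_invalid("n must be a count no larger than the number of cells")
  }
  preds <- names(stack$layers)
  missing <- setdiff(c("intercept", preds), names(truth$surfaces))
  if (length(missing)) {
    stop_invalid("truth surfaces missing: ", paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    cells <- sample(n_cells(grid), n)
    X <- vapply(stack$layers, `[`, numeric(n), cells)
    X <- matrix(X, nrow = n, dimnames = list(NULL, preds))
    B <- vapply(truth$surfaces[preds], `[`, numeric(n), cells)
    B <- matrix(B, nrow = n, dimnames = list(NULL, preds))
    z_signal <- truth$surfaces$intercept[cells] + rowSums(B * X)
    z <- z_signal + rnorm(n, 0, truth$noise_sd)
    if (truth$lambda != 0) {
      bad <- which(truth$lambda * z + 1 <= 0)
      for (i in bad) {
        ok <- FALSE
        for (try in seq_len(100L)) {
          zi <- z_signal[i] + rnorm(1L, 0, truth$noise_sd)
          if (truth$lambda * zi + 1 > 0) {
            z[i] <- zi
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_invalid("degenerate truth: Box-Cox inverse undefined after ",
                       "100 noise redraws at cell ", cells[i])
        }
      }
    }
    y <- boxcox_invert(z, truth$lambda)
    xy <- cell_coords(grid)[cells, , drop = FALSE]
    obs <- data.frame(id = seq_len(n), cell = cells,
                      x = xy[, 1L], y = xy[, 2L],
                      region = grid$region_labels[cells], stock = y)
    obs <- cbind(obs, as.data.frame(X))
    held <- data.frame(id = seq_len(n), cell = cells,
                       intercept = truth$surfaces$intercept[cells])
    held <- cbind(held, as.data.frame(B))
    held$z_signal <- z_signal
    held$z <- z
    list(observations = obs, truth = held)
  })
}

#' Expand observations into layered soil profiles
#'
#' Each observation becomes a profile whose layers tile 0-100 cm with
#' random interior boundaries; per-layer SOC concentration and bulk density
#' are drawn positive and the concentrations rescaled so that
#' [compute_profile_stock()] over 0-100 cm reproduces the observation's
#' stock exactly (about five layers per profile matches field sampling
#' practice).
#'
#' @param observations Observation data frame with `id`, `x`, `y`,
#'   `region`, `stock` columns.
#' @param layers_per_profile Number of depth layers per profile (>= 1).
#' @param seed Integer RNG seed.
#' @return A list of [soil_profile()] objects.
#' @export
generate_profiles <- function(observations, layers_per_profile = 5L, seed = 1L) {
  if (!is_count(layers_per_profile)) {
    stop_invalid("layers_per_profile must be a positive count")
  }
  L <- as.integer(layers_per_profile)
  with_seed(seed, {
    lapply(seq_len(nrow(observations)), function(i) {
      row <- observations[i, ]
      bounds <- c(0, sort(runif(L - 1L, 5, 95)), 100)
      top <- bounds[-(L + 1L)]
      bottom <- bounds[-1L]
      soc <- rlnorm(L, meanlog = 0, sdlog = 0.4)
      bd <- runif(L, 0.9, 1.6)
      implied <- sum(soc / 100 * bd * (bottom - top) * 100)
      soc <- soc * row$stock / implied
      soil_profile(id = row$id, x = row$x, y = row$y, region = row$region,
                   layers = data.frame(top = top, bottom = bottom,
                                       soc_pct = soc, bulk_density = bd))
    })
  })
}

#' Construct a decadal climate scenario set
#'
#' @param decades Strictly increasing vector of years.
#' @param overrides List (one element per decade, named by year) of named
#'   replacement layer vectors in grid cell order.
#' @param grid The [landscape_grid()] the override layers live on.
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(decades, overrides, grid) {
  if (length(decades) < 1L || is.unsorted(decades, strictly = TRUE)) {
    stop_invalid("decades must be strictly increasing years")
  }
  if (length(overrides) != length(decades) ||
      !identical(names(overrides), as.character(decades))) {
    stop_invalid("overrides must be named by decade year")
  }
  nc <- n_cells(grid)
  for (ov in overrides) {
    if (!all(vapply(ov, length, 0L) == nc)) {
      stop_invalid("override layers must be co-registered with the grid")
    }
  }
  structure(list(decades = decades, overrides = overrides, grid = grid),
            class = "scenario_set")
}

#' Generate decadal future-climate override layers
#'
#' Emulates downscaled earth-system-model projections: decade `i`'s
#' temperature layer is the baseline plus `i * temp_delta_per_decade` and an
#' optional smooth zero-mean spatial perturbation; precipitation is the
#' baseline scaled by `precip_factor_per_decade^i`, floored at zero. All
#' other layers are untouched (they are held constant during projection).
#'
#' @param stack Baseline [predictor_stack()] containing the named climate
#'   layers.
#' @param decades Years, e.g. `seq(2030, 2100, by = 10)`.
#' @param temp_delta_per_decade Additive warming per decade (degrees C).
#' @param precip_factor_per_decade Multiplicative precipitation change per
#'   decade (1 = none).
#' @param seed Integer RNG seed (used only when `perturbation_sd > 0`).
#' @param temp_name,precip_name Names of the climate layers in `stack`.
#' @param perturbation_sd Standard deviation of the smooth spatial
#'   perturbation added to each decade's temperature layer; 0 disables it.
#' @param perturbation_smoothness Correlation length of the perturbation.
#' @return A [scenario_set()].
#' @export
generate_future_climate <- function(stack, decades,
                                    temp_delta_per_decade = 0.5,
                                    precip_factor_per_decade = 1,
                                    seed = 1L,
                                    temp_name = "temperature",
                                    precip_name = "precipitation",
                                    perturbation_sd = 0,
                                    perturbation_smoothness = 5) {
  for (nm in c(temp_name, precip_name)) {
    if (!nm %in% names(stack$layers)) {
      stop_invalid("missing layer in stack: ", nm)
    }
  }
  grid <- stack$grid
  base_t <- stack$layers[[temp_name]]
  base_p <- stack$layers[[precip_name]]
  with_seed(seed, {
    overrides <- lapply(seq_along(decades), function(i) {
      pert <- if (perturbation_sd > 0) {
        perturbation_sd * smooth_field(grid, perturbation_smoothness)
      } else 0
      scaled_p <- base_p * precip_factor_per_decade^i
      # the zero floor is a physical guard: it can only bind when the
      # baseline itself has negative values (e.g. a standardized anomaly
      # field), where clipping would distort the prescribed scaling
      if (min(base_p) >= 0) scaled_p <- pmax(scaled_p, 0)
      out <- list(base_t + i * temp_delta_per_decade + pert, scaled_p)
      names(out) <- c(temp_name, precip_name)
      out
    })
    names(overrides) <- as.character(decades)
    scenario_set(decades, overrides, grid)
  })
}
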