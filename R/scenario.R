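#' Construct a stock map
#'
#' A gridded SOC stock surface (Mg/ha) on a [landscape_grid()], with `NA`
#' marking missing cells, plus a scenario tag and year.
#'
#' @param grid A [landscape_grid()].
#' @param values Numeric vector in grid cell order; non-missing values
#'   must be non-negative.
#' @param year Calendar year of the map (`NA` for baseline).
#' @param scenario Free-text scenario tag (e.g. `"baseline"`, `"ssp585"`).
#' @return An object of class `stock_map`.
#' @export
stock_map <- function(grid, values, year = NA_integer_, scenario = "baseline") {
  if (length(values) != n_cells(grid)) {
    stop_invalid("values must supply one stock per cell")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_invalid("stocks must be non-negative where present")
  }
  structure(list(grid = grid, values = as.numeric(values),
                 year = year, scenario = scenario),
            class = "stock_map")
}

#' @export
print.stock_map <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("stock_map [%s%s]: %d x %d cells, %d missing\n",
              x$scenario, if (!is.na(x$year)) paste0(", ", x$year) else "",
              x$grid$nx, x$grid$ny, sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  stocks %.1f-%.1f Mg/ha (mean %.1f)\n",
                min(x$values[ok]), max(x$values[ok]), mean(x$values[ok])))
  }
  invisible(x)
}

# Predictor matrix for every grid cell, with scenario overrides applied.
assemble_cell_predictors <- function(fit, baseline, overrides = list()) {
  layers <- baseline$layers
  for (nm in names(overrides)) layers[[nm]] <- overrides[[nm]]
  missing <- setdiff(fit$predictor_names, names(layers))
  if (length(missing)) {
    stop_invalid("stack lacks fitted predictor layer(s): ",
                 paste(missing, collapse = ", "))
  }
  do.call(cbind, setNames(
    lapply(fit$predictor_names, function(nm) layers[[nm]]),
    fit$predictor_names))
}

#' Project SOC stocks under a climate scenario (space-for-time)
#'
#' Holds every predictor layer fixed except the scenario's overridden
#' layers (temperature and precipitation), re-evaluates the fitted local
#' coefficient field at every cell centre, and back-transforms to Mg/ha.
#' The coefficient field itself is held fixed: the scenario changes
#' predictor values only. Cells with any missing predictor, or whose
#' transformed prediction falls outside the Box-Cox inverse domain,
#' come out missing.
#'
#' @param fit A [gwr_fit()] whose predictors all exist as stack layers.
#' @param baseline Baseline [predictor_stack()].
#' @param scenario A [scenario_set()] co-registered with the baseline, or
#'   `NULL` for the baseline map itself.
#' @param decade Year to project (must be in `scenario$decades`).
#' @param transform The [fit_boxcox()] transform used when fitting.
#' @param coefficients Optional precomputed [local_coefficients()] matrix
#'   for the cell centres (reused across decades by [decadal_series()]).
#' @return A [stock_map()].
#' @export
project_scenario <- function(fit, baseline, scenario = NULL, decade = NA,
                             transform = NULL, coefficients = NULL) {
  grid <- baseline$grid
  overrides <- list()
  if (!is.null(scenario)) {
    if (!same_geometry(grid, scenario$grid)) {
      stop_invalid("co-registration error: scenario grid differs from baseline")
    }
    key <- as.character(decade)
    if (!key %in% names(scenario$overrides)) {
      stop_invalid("scenario has no overrides for decade ", decade)
    }
    overrides <- scenario$overrides[[key]]
    extra <- setdiff(names(overrides), names(baseline$layers))
    if (length(extra)) {
      stop_invalid("override layer(s) absent from baseline stack: ",
                   paste(extra, collapse = ", "))
    }
  }
  Xc <- assemble_cell_predictors(fit, baseline, overrides)
  B <- coefficients %||% local_coefficients(fit, cell_coords(grid))
  z <- B[, 1L] + rowSums(B[, -1L, drop = FALSE] * Xc)
  vals <- if (is.null(transform)) z else {
    boxcox_invert(z, transform$lambda, missing_on_domain = TRUE)
  }
  stock_map(grid, vals,
            year = if (is.na(decade)) NA_integer_ else as.integer(decade),
            scenario = if (is.null(scenario)) "baseline" else "scenario")
}

#' Cell-wise difference of two stock maps
#'
#' @param a,b [stock_map()]s on identical geometry.
#' @return A [stock_map()] of `a - b` (missing wherever either side is),
#'   tagged with both scenario names. Differences may be negative; the
#'   non-negativity check applies to stocks, not to changes, so the result
#'   carries class `stock_map` without re-validation.
#' @export
difference_map <- function(a, b) {
  if (!same_geometry(a$grid, b$grid)) {
    stop_invalid("co-registration error: map geometries differ")
  }
  out <- a
  out$values <- a$values - b$values
  out$scenario <- paste0(a$scenario, " - ", b$scenario)
  out$year <- a$year
  out
}

#' Zonal aggregation of a stock map to regions
#'
#' Per-region mean stock over non-missing cells, region area from the
#' non-missing cell count, and total stock in Tg via the unit chain
#' Mg/ha x cell-area(ha) x 1e-6, plus a grand-total row. Regions whose
#' cells are all missing get a missing mean and zero total.
#'
#' @param map A [stock_map()].
#' @param regions Integer label vector per cell; defaults to the map
#'   grid's region labels.
#' @param cell_size Cell edge in metres; defaults to the map grid's.
#' @return Data frame with columns `region`, `n_cells`, `mean_stock_mg_ha`,
#'   `area_ha`, `total_tg`; the last row is the grand total
#'   (`region = "total"`).
#' @export
aggregate_by_region <- function(map, regions = NULL, cell_size = NULL) {
  regions <- regions %||% map$grid$region_labels
  cell_size <- cell_size %||% map$grid$cell_size
  if (length(regions) != length(map$values)) {
    stop_invalid("co-registration error: label grid does not match the map")
  }
  cell_ha <- cell_size^2 / 1e4
  rows <- lapply(sort(unique(regions)), function(r) {
    v <- map$values[regions == r]
    ok <- !is.na(v)
    data.frame(region = as.character(r), n_cells = sum(ok),
               mean_stock_mg_ha = if (any(ok)) mean(v[ok]) else NA_real_,
               area_ha = sum(ok) * cell_ha,
               total_tg = sum(v[ok]) * cell_ha * 1e-6)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(map$values)
  total <- data.frame(region = "total", n_cells = sum(ok),
                      mean_stock_mg_ha = if (any(ok)) mean(map$values[ok]) else NA_real_,
                      area_ha = sum(ok) * cell_ha,
                      total_tg = sum(map$values[ok]) * cell_ha * 1e-6)
  rbind(out, total)
}

#' Decadal SOC stock series under a scenario
#'
#' Projects every decade of the scenario and summarises each map:
#' min/max/mean over non-missing cells (Mg/ha) and the total in Pg
#' (`Tg x 1e-3`). The local coefficient field is computed once and reused
#' across decades.
#'
#' @param fit A [gwr_fit()].
#' @param baseline Baseline [predictor_stack()].
#' @param scenario A non-empty [scenario_set()].
#' @param transform The fitted Box-Cox transform.
#' @return Data frame with one row per decade: `year`, `min_mg_ha`,
#'   `max_mg_ha`, `mean_mg_ha`, `total_pg`.
#' @export
decadal_series <- function(fit, baseline, scenario, transform) {
  if (length(scenario$decades) < 1L) stop_invalid("scenario is empty")
  B <- local_coefficients(fit, cell_coords(baseline$grid))
  cell_ha <- baseline$grid$cell_size^2 / 1e4
  rows <- lapply(scenario$decades, function(yr) {
    m <- project_scenario(fit, baseline, scenario, yr, transform,
                          coefficients = B)
    v <- m$values[!is.na(m$values)]
    data.frame(year = yr, min_mg_ha = min(v), max_mg_ha = max(v),
               mean_mg_ha = mean(v),
               total_pg = sum(v) * cell_ha * 1e-6 * 1e-3)
  })
  do.call(rbind, rows)
}

#' Compare a stock map against a coarser external SOC grid
#'
#' Block-averages the fine map onto the external grid (mean of the fine
#' cells whose centres fall inside each coarse cell) and differences the
#' result against the external values, mirroring comparison against a
#' coarse earth-system-model SOC raster.
#'
#' @param ours Fine-resolution [stock_map()].
#' @param external Coarse [stock_map()] with its own geometry, overlapping
#'   ours.
#' @return A [stock_map()] on the external geometry holding
#'   `block_mean(ours) - external`; coarse cells covering no fine cell are
#'   missing.
#' @export
compare_external_soc <- function(ours, external) {
  fine <- ours$grid
  coarse <- external$grid
  xy <- cell_coords(fine)
  # index of the coarse cell containing each fine cell centre
  ix <- floor((xy[, 1L] - (coarse$origin_x - coarse$cell_size / 2)) /
                coarse$cell_size) + 1
  iy <- floor((xy[, 2L] - (coarse$origin_y - coarse$cell_size / 2)) /
                coarse$cell_size) + 1
  inside <- ix >= 1 & ix <= coarse$nx & iy >= 1 & iy <= coarse$ny
  if (!any(inside)) {
    stop_invalid("co-registration error: grids do not overlap")
  }
  cellidx <- (iy - 1) * coarse$nx + ix
  agg <- rep(NA_real_, n_cells(coarse))
  ok <- inside & !is.na(ours$values)
  if (any(ok)) {
    sums <- tapply(ours$values[ok], cellidx[ok], mean)
    agg[as.integer(names(sums))] <- as.numeric(sums)
  }
  out <- external
  out$values <- agg - external$values
  out$scenario <- paste0(ours$scenario, " - ", external$scenario)
  out
}
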