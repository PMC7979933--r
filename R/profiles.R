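#' Construct a soil profile
#'
#' A georeferenced pedon: ordered depth layers, each with a SOC
#' concentration (% by mass) and bulk density (g/cm^3). Layers must be
#' sorted by top depth and non-overlapping.
#'
#' @param id Profile identifier.
#' @param x,y Planar coordinates in metres (or lon/lat degrees).
#' @param region Ecoregion label.
#' @param layers Data frame with columns `top`, `bottom` (cm below
#'   surface), `soc_pct` and `bulk_density`.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(id, x, y, region, layers) {
  need <- c("top", "bottom", "soc_pct", "bulk_density")
  if (!all(need %in% names(layers))) {
    stop_invalid("layers must have columns: ", paste(need, collapse = ", "))
  }
  layers <- layers[order(layers$top), need]
  if (any(layers$top < 0) || any(layers$bottom <= layers$top)) {
    stop_invalid("layer depths must satisfy 0 <= top < bottom")
  }
  if (nrow(layers) > 1L &&
      any(layers$top[-1L] < layers$bottom[-nrow(layers)] - 1e-9)) {
    stop_invalid("layers overlap")
  }
  if (any(layers$soc_pct < 0)) stop_invalid("soc_pct must be non-negative")
  if (any(layers$bulk_density <= 0)) stop_invalid("bulk_density must be positive")
  structure(list(id = id, x = x, y = y, region = region, layers = layers),
            class = "soil_profile")
}

#' Fixed-depth SOC stock of a profile
#'
#' Computes the 0-`depth_limit` cm stock by the standard
#' concentration x density x thickness product:
#' `stock = sum (soc_pct/100) * bulk_density * thickness_cm * 100` Mg/ha,
#' where each layer contributes its overlap with the depth window
#' (layers straddling the limit contribute pro-rata, layers below it
#' contribute nothing). No coarse-fragment correction is applied;
#' concentrations are taken on a fine-earth basis.
#'
#' @param profile A [soil_profile()].
#' @param depth_limit Lower boundary of the accounting window in cm.
#' @return Stock in Mg/ha.
#' @examples
#' p <- soil_profile(1, 0, 0, 1, data.frame(top = 0, bottom = 100,
#'                                          soc_pct = 1, bulk_density = 1))
#' compute_profile_stock(p)  # 100 Mg/ha
#' @export
compute_profile_stock <- function(profile, depth_limit = 100) {
  l <- profile$layers
  thick <- pmax(0, pmin(l$bottom, depth_limit) - pmax(l$top, 0))
  if (all(thick <= 0)) {
    stop_invalid("no layer intersects the window [0, ", depth_limit, ") cm")
  }
  sum(l$soc_pct / 100 * l$bulk_density * thick * 100)
}

#' Per-region interquartile-range outlier filtering
#'
#' Within each ecoregion, removes rows whose stock falls outside
#' `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed by linear
#' interpolation between order statistics. The pass is single: fences are
#' computed once on the input and not re-derived after removal, so the
#' operation is deliberately not idempotent. Regions with fewer than 4
#' rows pass through unfiltered with a warning.
#'
#' @param table Observation data frame with `region` and `stock` columns.
#' @param k Fence multiplier (default 1.5).
#' @param stock_col,region_col Column names to use.
#' @return A list with `kept` and `removed` data frames; together they
#'   partition the input, in its original row order.
#' @export
filter_outliers_iqr <- function(table, k = 1.5,
                                stock_col = "stock", region_col = "region") {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_invalid("table must be a non-empty data frame")
  }
  if (!all(c(stock_col, region_col) %in% names(table))) {
    stop_invalid("table must have columns '", stock_col, "' and '",
                 region_col, "'")
  }
  s <- table[[stock_col]]
  keep <- rep(TRUE, nrow(table))
  for (r in unique(table[[region_col]])) {
    idx <- which(table[[region_col]] == r)
    if (length(idx) < 4L) {
      warning("region ", r, " has fewer than 4 rows; passed through unfiltered",
              call. = FALSE)
      next
    }
    q <- quantile(s[idx], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    keep[idx] <- s[idx] >= q[1L] - k * iqr & s[idx] <= q[2L] + k * iqr
  }
  list(kept = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE])
}
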