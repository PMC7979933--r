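`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All exported generators route their randomness through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Pairwise distances from one point to a coordinate matrix. Planar input
# uses Euclidean distance; lon/lat input uses the haversine great-circle
# distance (metres).
point_distances <- function(point, coords, lonlat = FALSE) {
  if (lonlat) {
    geosphere::distHaversine(point, coords)
  } else {
    sqrt((coords[, 1L] - point[1L])^2 + (coords[, 2L] - point[2L])^2)
  }
}

distance_matrix <- function(coords, lonlat = FALSE) {
  if (lonlat) {
    geosphere::distm(coords, fun = geosphere::distHaversine)
  } else {
    as.matrix(dist(coords))
  }
}

domain_diagonal <- function(coords, lonlat = FALSE) {
  lo <- c(min(coords[, 1L]), min(coords[, 2L]))
  hi <- c(max(coords[, 1L]), max(coords[, 2L]))
  if (lonlat) geosphere::distHaversine(lo, hi) else sqrt(sum((hi - lo)^2))
}
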