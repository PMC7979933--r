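# Raster IO uses the ESRI ASCII grid format (.asc): a plain-text header
# (ncols/nrows/xllcenter/yllcenter/cellsize/nodata_value) followed by rows
# of values from the top row down. Values are written with enough digits
# to round-trip doubles.

write_asc <- function(values, grid, path, nodata = -9999) {
  m <- vec_to_mat(values, grid)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcenter", format(grid$origin_x, digits = 15)),
    paste("yllcenter", format(grid$origin_y, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("nodata_value", nodata)
  ), con)
  for (iy in rev(seq_len(grid$ny))) {
    writeLines(paste(format(m[iy, ], digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

read_asc <- function(path) {
  if (!file.exists(path)) stop_invalid("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcenter", "yllcenter", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_invalid("malformed ASCII grid header in ", path,
                 " (cell-centre registration required)")
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  if (length(vals) != nx * ny) {
    stop_invalid("raster body of ", path, " has ", length(vals),
                 " values, expected ", nx * ny)
  }
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)[rev(seq_len(ny)), ,
                                                        drop = FALSE]
  v <- mat_to_vec(m)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) v[v == nodata] <- NA_real_
  list(values = v, nx = nx, ny = ny, cell_size = hdr$cellsize,
       origin_x = hdr$xllcenter, origin_y = hdr$yllcenter)
}

#' Write and read a predictor stack
#'
#' A stack serializes as one `.asc` raster per layer plus a `regions.asc`
#' label raster and a YAML manifest (`manifest.yaml`) recording the grid
#' geometry, the layer-name-to-file mapping, and which layers are
#' indicators.
#'
#' @param stack A [predictor_stack()].
#' @param dir Directory to write into (created if needed).
#' @param manifest_path Path to a manifest written by [write_stack()].
#' @return `write_stack`: the manifest path, invisibly. `read_stack`: the
#'   reconstructed [predictor_stack()].
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- stack$grid
  files <- list()
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".asc")
    write_asc(stack$layers[[nm]], grid, file.path(dir, f))
    files[[nm]] <- f
  }
  write_asc(grid$region_labels, grid, file.path(dir, "regions.asc"))
  manifest <- list(
    grid = list(nx = grid$nx, ny = grid$ny, cell_size = grid$cell_size,
                origin_x = grid$origin_x, origin_y = grid$origin_y),
    layers = files,
    indicator = as.list(stack$indicator),
    categorical = stack$categorical,
    region_file = "regions.asc"
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_invalid("manifest not found: ", manifest_path)
  }
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  g <- man$grid
  reg <- read_asc(file.path(dir, man$region_file))
  grid <- landscape_grid(g$nx, g$ny, g$cell_size, as.integer(reg$values),
                         g$origin_x, g$origin_y)
  layers <- list()
  for (nm in names(man$layers)) {
    f <- file.path(dir, man$layers[[nm]])
    if (!file.exists(f)) stop_invalid("manifest references a missing file: ", f)
    r <- read_asc(f)
    if (r$nx != grid$nx || r$ny != grid$ny ||
        !isTRUE(all.equal(r$cell_size, grid$cell_size))) {
      stop_invalid("layer ", nm, " geometry differs from the manifest grid")
    }
    layers[[nm]] <- r$values
  }
  predictor_stack(grid, layers,
                  indicator = as.character(unlist(man$indicator)),
                  categorical = man$categorical %||% list())
}

#' Write and read a stock map raster
#'
#' @param map A [stock_map()].
#' @param path Output `.asc` path.
#' @param year,scenario Metadata to attach on read (the ASCII grid format
#'   carries none).
#' @param region_labels Optional label vector for the reconstructed grid;
#'   defaults to a single region.
#' @return `write_stock_map`: the path, invisibly. `read_stock_map`: a
#'   [stock_map()].
#' @export
write_stock_map <- function(map, path) {
  write_asc(map$values, map$grid, path)
  invisible(path)
}

#' @rdname write_stock_map
#' @export
read_stock_map <- function(path, year = NA_integer_, scenario = "baseline",
                           region_labels = NULL) {
  r <- read_asc(path)
  grid <- landscape_grid(r$nx, r$ny, r$cell_size,
                         region_labels %||% rep(1L, r$nx * r$ny),
                         r$origin_x, r$origin_y)
  stock_map(grid, r$values, year = year, scenario = scenario)
}

#' Write and read soil profiles as CSV
#'
#' One row per layer: `profile_id, x, y, region, top, bottom, soc_pct,
#' bulk_density`. On read, rows with a missing bulk density are dropped
#' with a message (bulk-density imputation is out of scope) and rows with
#' a non-positive bulk density or inverted depths are rejected with their
#' line numbers.
#'
#' @param profiles List of [soil_profile()]s.
#' @param path CSV path.
#' @return `write_profiles`: the path, invisibly. `read_profiles`: a list
#'   of [soil_profile()]s.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(data.frame(profile_id = p$id, x = p$x, y = p$y, region = p$region),
          p$layers)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_invalid("profile file not found: ", path)
  d <- read.csv(path)
  need <- c("profile_id", "x", "y", "region", "top", "bottom",
            "soc_pct", "bulk_density")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_invalid("profile CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  na_bd <- is.na(d$bulk_density)
  if (any(na_bd)) {
    message(sum(na_bd), " layer row(s) with missing bulk density dropped")
    d <- d[!na_bd, , drop = FALSE]
  }
  bad <- which(d$bulk_density <= 0 | d$soc_pct < 0 | d$bottom <= d$top |
                 d$top < 0)
  if (length(bad)) {
    stop_invalid("invalid profile rows (data line ",
                 paste(bad, collapse = ", "),
                 "): bulk density must be positive, soc_pct non-negative, ",
                 "and 0 <= top < bottom")
  }
  lapply(split(d, d$profile_id), function(g) {
    soil_profile(id = g$profile_id[1L], x = g$x[1L], y = g$y[1L],
                 region = g$region[1L],
                 layers = g[, c("top", "bottom", "soc_pct", "bulk_density")])
  })
}
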