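#' Per-region residual bias
#'
#' Signed mean residual (predicted - observed, Mg/ha) per ecoregion, and
#' the bias percentage `|mean residual| / mean observed stock x 100`. The
#' sign is reported separately from the percentage. Pairs with a missing
#' prediction are dropped per region; regions with no usable pairs are
#' flagged missing.
#'
#' @param predicted,observed Co-indexed stock vectors in Mg/ha.
#' @param regions Region label per observation.
#' @return Data frame with `region`, `n`, `mean_observed`,
#'   `mean_residual`, `bias_pct`.
#' @export
region_bias <- function(predicted, observed, regions) {
  if (length(predicted) != length(observed) ||
      length(observed) != length(regions)) {
    stop_invalid("predicted, observed and regions must be co-indexed")
  }
  rows <- lapply(sort(unique(regions)), function(r) {
    i <- which(regions == r & !is.na(predicted) & !is.na(observed))
    if (!length(i)) {
      return(data.frame(region = as.character(r), n = 0L,
                        mean_observed = NA_real_, mean_residual = NA_real_,
                        bias_pct = NA_real_))
    }
    mo <- mean(observed[i])
    mr <- mean(predicted[i] - observed[i])
    data.frame(region = as.character(r), n = length(i), mean_observed = mo,
               mean_residual = mr, bias_pct = abs(mr) / mo * 100)
  })
  do.call(rbind, rows)
}

#' Test-set coefficient of determination
#'
#' `R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, computed on
#' whatever scale the vectors are supplied on (here, back-transformed
#' Mg/ha stocks). Pairs with a missing prediction are dropped with a
#' message.
#'
#' @param predicted,observed Co-indexed vectors, at least 3 usable pairs.
#' @return The R-squared value (can be negative for a model worse than
#'   the mean).
#' @export
test_r2 <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed)
  if (sum(!ok)) message(sum(!ok), " pair(s) with missing values dropped")
  predicted <- predicted[ok]
  observed <- observed[ok]
  if (length(observed) < 3L) stop_invalid("need at least 3 usable pairs")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop_invalid("undefined R2: observed values have zero variance")
  1 - sum((observed - predicted)^2) / tss
}

#' PCA of regional mean GWR coefficients
#'
#' Averages the local coefficients over calibration points per ecoregion,
#' standardizes the columns, and eigen-decomposes their correlation
#' matrix. Loadings are the orthonormal eigenvectors, region scores the
#' projections of the standardized regional means, and the
#' explained-variance fractions the eigenvalues over their sum — the view
#' relating which predictors control SOC in which regions.
#'
#' @param fit A [gwr_fit()].
#' @param regions Region label per calibration point (>= 3 regions).
#' @param include_intercept Include the local intercept as a column
#'   (default `FALSE`: the analysis relates predictors to regions).
#' @return An object of class `coefficient_pca`: `means` (region x
#'   predictor matrix), `loadings`, `scores`, `explained_variance`.
#' @export
coefficient_pca <- function(fit, regions, include_intercept = FALSE) {
  B <- fit$local_coefficients
  if (!include_intercept) B <- B[, -1L, drop = FALSE]
  if (ncol(B) < 2L) stop_invalid("need at least 2 predictors for a PCA")
  if (length(regions) != nrow(B)) {
    stop_invalid("regions must label every calibration point")
  }
  M <- aggregate(B, by = list(region = regions), FUN = mean)
  rn <- as.character(M$region)
  M <- as.matrix(M[, -1L, drop = FALSE])
  rownames(M) <- rn
  if (nrow(M) < 3L) stop_invalid("need at least 3 regions for a PCA")
  sds <- apply(M, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping constant coefficient column(s): ",
            paste(colnames(M)[sds == 0], collapse = ", "), call. = FALSE)
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) < 2L) stop_invalid("fewer than 2 varying coefficient columns")
  }
  S <- scale(M)
  C <- cor(M)
  e <- eigen(C, symmetric = TRUE)
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(M), paste0("PC", seq_len(ncol(loadings))))
  scores <- S %*% loadings
  structure(list(means = M, loadings = loadings, scores = scores,
                 explained_variance = e$values / sum(e$values),
                 eigenvalues = e$values),
            class = "coefficient_pca")
}

#' @export
print.coefficient_pca <- function(x, ...) {
  cat(sprintf("PCA of %d regional mean coefficients over %d predictor(s)\n",
              nrow(x$means), ncol(x$means)))
  ev <- round(100 * x$explained_variance[seq_len(min(3L, length(x$explained_variance)))], 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  invisible(x)
}
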