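#' Assemble the report bundle
#'
#' Writes the pipeline's tabular products as CSV files under `dir`, plus a
#' structured plain-text summary: the per-region stock/residual table with
#' scenario totals, the decadal series, the screening report (dropped
#' pairs, selected predictors), the GWR summary and local coefficients,
#' and the coefficient-PCA tables. Numbers are written at full double
#' precision so reruns are byte-comparable.
#'
#' @param artifacts Named list with required elements `observations`,
#'   `screening` (list with `dropped_by_correlation` and `selection`),
#'   `fit` (a [gwr_fit()]), `region_summary`, `decadal_series`, `bias`;
#'   optional `pca` (a [coefficient_pca()]) and `test_r2`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
build_report <- function(artifacts, dir) {
  required <- c("observations", "screening", "fit", "region_summary",
                "decadal_series", "bias")
  miss <- setdiff(required, names(artifacts))
  if (length(miss)) {
    stop_invalid("missing report input(s): ", paste(miss, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(artifacts$observations, "observations.csv")
  put(artifacts$screening$dropped_by_correlation, "screening_dropped.csv")
  sel <- artifacts$screening$selection
  put(data.frame(predictor = if (length(sel$predictors)) sel$predictors else NA,
                 r2 = sel$r2, adj_r2 = sel$adj_r2),
      "screening_selected.csv")
  fit <- artifacts$fit
  put(data.frame(k_selected = fit$k_selected, trace_S = fit$trace_S,
                 sigma_hat = fit$sigma_hat, aicc = fit$aicc,
                 kernel = fit$config$kernel,
                 n_calibration = nrow(fit$coords)),
      "gwr_summary.csv")
  put(cbind(data.frame(x = fit$coords[, 1L], y = fit$coords[, 2L],
                       bandwidth = fit$bandwidths,
                       residual = fit$residuals),
            as.data.frame(fit$local_coefficients)),
      "gwr_coefficients.csv")
  put(artifacts$region_summary, "region_summary.csv")
  put(artifacts$decadal_series, "decadal_series.csv")
  put(artifacts$bias, "region_bias.csv")
  if (!is.null(artifacts$pca)) {
    p <- artifacts$pca
    put(cbind(predictor = rownames(p$loadings), as.data.frame(p$loadings)),
        "pca_loadings.csv")
    put(cbind(region = rownames(p$scores), as.data.frame(p$scores)),
        "pca_scores.csv")
    put(data.frame(component = seq_along(p$explained_variance),
                   eigenvalue = p$eigenvalues,
                   explained_variance = p$explained_variance),
        "pca_variance.csv")
  }
  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    "socgwr report bundle",
    sprintf("observations: %d", nrow(artifacts$observations)),
    sprintf("selected predictors: %s",
            paste(sel$predictors, collapse = ", ")),
    sprintf("GWR: k = %s, trace(S) = %.2f, AICc = %.2f",
            as.character(fit$k_selected), fit$trace_S, fit$aicc),
    if (!is.null(artifacts$test_r2)) {
      sprintf("test-set R2 (Mg/ha scale): %.4f", artifacts$test_r2)
    },
    sprintf("files: %s", paste(basename(files), collapse = ", "))
  )
  writeLines(lines, summary_path)
  invisible(c(files, summary_path))
}
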