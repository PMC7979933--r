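#' Run the full synthetic SOC analysis pipeline
#'
#' Chains every stage on a synthetic landscape with known ground truth:
#' landscape and predictor generation, observation sampling and profile
#' expansion, fixed-depth stock computation, per-region IQR outlier
#' removal, train/test split, Box-Cox fitting on the training partition,
#' correlation pruning and best-subset screening, GWR fitting with
#' AICc-selected adaptive bandwidth, test-set diagnostics, baseline stock
#' mapping, decadal scenario projection, zonal aggregation, coefficient
#' PCA, and the report bundle. Given the same configuration the run is
#' fully deterministic: every stage draws from a stream derived from
#' `config$seed`, and all outputs land under `output_dir`.
#'
#' @param config A `run_config` from [default_config()] or
#'   [read_config()].
#' @param output_dir Output directory; overrides `config$output_dir`.
#'   `NULL` skips writing and returns artifacts only.
#' @return A named list of pipeline artifacts, invisibly when writing.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  cfg <- validate_config(config)
  out <- output_dir %||% cfg$output_dir
  seed <- cfg$seed

  # --- simulate -------------------------------------------------------
  grid <- generate_landscape(cfg$landscape$nx, cfg$landscape$ny,
                             cfg$landscape$cell_size, cfg$landscape$n_regions,
                             seed = seed + 1L)
  stack <- generate_predictor_fields(grid, cfg$predictors$continuous,
                                     cfg$predictors$categorical,
                                     smoothness = cfg$predictors$smoothness,
                                     seed = seed + 2L)
  truth <- generate_truth(grid, names(stack$layers),
                          smoothness = cfg$truth$smoothness,
                          intercept_mean = cfg$truth$intercept_mean,
                          intercept_sd = cfg$truth$intercept_sd,
                          coef_mean = cfg$truth$coef_mean,
                          coef_sd = cfg$truth$coef_sd,
                          lambda = cfg$truth$lambda,
                          noise_sd = cfg$truth$noise_sd,
                          seed = seed + 3L)
  gen <- generate_observations(grid, stack, truth, cfg$observations$n,
                               seed = seed + 4L)
  profiles <- generate_profiles(gen$observations,
                                cfg$profiles$layers_per_profile,
                                seed = seed + 5L)

  # --- preprocess: stocks from profiles, outliers, transform ----------
  obs <- gen$observations
  obs$stock <- vapply(profiles, compute_profile_stock, numeric(1L))
  filt <- filter_outliers_iqr(obs, k = cfg$outliers$k)
  split <- train_test_split(filt$kept, cfg$split$train_fraction,
                            seed = seed + 6L)
  bc <- fit_boxcox(split$train$stock)
  z_train <- boxcox_apply(split$train$stock, bc$lambda)

  # --- screen ---------------------------------------------------------
  pred_names <- names(stack$layers)
  pruned <- correlation_prune(split$train[pred_names],
                              threshold = cfg$screening$cor_threshold,
                              priority = cfg$screening$priority)
  lin <- linearity_screen(pruned$data, z_train)
  selection <- best_subset_select(pruned$data, z_train,
                                  alpha = cfg$screening$alpha)
  if (!length(selection$predictors)) {
    stop_invalid("screening selected the null model; ",
                 "no geographically weighted fit is possible")
  }

  # --- fit ------------------------------------------------------------
  gcfg <- gwr_config(kernel = cfg$gwr$kernel,
                     k_range = if (!is.null(cfg$gwr$k_min)) {
                       c(cfg$gwr$k_min, cfg$gwr$k_max %||% nrow(split$train))
                     },
                     ridge_jitter = cfg$gwr$ridge_jitter)
  fit <- fit_gwr(as.matrix(split$train[selection$predictors]), z_train,
                 as.matrix(split$train[c("x", "y")]), gcfg)

  # --- predict & diagnose --------------------------------------------
  pred_test <- predict_gwr(fit, as.matrix(split$test[selection$predictors]),
                           as.matrix(split$test[c("x", "y")]), bc)
  r2 <- test_r2(pred_test, split$test$stock)
  bias <- region_bias(pred_test, split$test$stock, split$test$region)

  cell_B <- local_coefficients(fit, cell_coords(grid))
  baseline_map <- project_scenario(fit, stack, transform = bc,
                                   coefficients = cell_B)
  region_summary <- aggregate_by_region(baseline_map)

  # --- project --------------------------------------------------------
  scen <- generate_future_climate(
    stack, cfg$scenario$decades,
    temp_delta_per_decade = cfg$scenario$temp_delta_per_decade,
    precip_factor_per_decade = cfg$scenario$precip_factor_per_decade,
    perturbation_sd = cfg$scenario$perturbation_sd,
    seed = seed + 7L)
  series <- decadal_series(fit, stack, scen, bc)
  last <- max(scen$decades)
  final_map <- project_scenario(fit, stack, scen, last, bc,
                                coefficients = cell_B)
  change_map <- difference_map(final_map, baseline_map)

  pca <- if (length(selection$predictors) >= 2L &&
             length(unique(split$train$region)) >= 3L) {
    coefficient_pca(fit, split$train$region)
  }

  artifacts <- list(
    grid = grid, stack = stack, truth = gen$truth, profiles = profiles,
    observations = filt$kept, removed = filt$removed,
    split = split, boxcox = bc,
    screening = list(correlation = pruned$report,
                     dropped_by_correlation = pruned$report$dropped_by_correlation,
                     linearity = lin, selection = selection),
    fit = fit, test_predictions = pred_test, test_r2 = r2, bias = bias,
    baseline_map = baseline_map, final_map = final_map,
    change_map = change_map, region_summary = region_summary,
    decadal_series = series, scenario = scen, pca = pca
  )

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_stack(stack, file.path(out, "stack"))
    write_profiles(profiles, file.path(out, "profiles.csv"))
    write_stock_map(baseline_map, file.path(out, "stock_baseline.asc"))
    write_stock_map(final_map,
                    file.path(out, sprintf("stock_%d.asc", last)))
    write_stock_map(change_map,
                    file.path(out, sprintf("stock_change_%d.asc", last)))
    build_report(artifacts, file.path(out, "report"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("socgwr")),
      seed = cfg$seed,
      stage_seeds = as.list(setNames(seed + 1:7,
                                     c("landscape", "predictors", "truth",
                                       "observations", "profiles", "split",
                                       "scenario"))),
      thresholds = list(iqr_k = cfg$outliers$k,
                        cor_threshold = cfg$screening$cor_threshold,
                        alpha = cfg$screening$alpha,
                        train_fraction = cfg$split$train_fraction),
      boxcox_lambda = bc$lambda,
      gwr = list(kernel = fit$config$kernel, k_selected = fit$k_selected),
      selected_predictors = selection$predictors
    )
    yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))
    return(invisible(artifacts))
  }
  artifacts
}
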