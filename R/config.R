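#' Default run configuration
#'
#' All analysis tunables with their standard values: IQR fence multiplier
#' 1.5, correlation-pruning threshold 0.70, significance level 0.05,
#' training fraction 0.75. The synthetic-landscape block defines the
#' simulated study conditions (grid size, predictor set, coefficient
#' smoothness, response skew, sampling density); the scenario block the
#' decadal climate drift.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    landscape = list(nx = 30L, ny = 30L, cell_size = 800, n_regions = 5L),
    predictors = list(
      continuous = c("temperature", "precipitation", "ndvi"),
      categorical = c(soil_order = 3L),
      smoothness = 6
    ),
    truth = list(smoothness = 10, intercept_mean = 7, intercept_sd = 0.8,
                 coef_mean = c(temperature = -0.5, precipitation = 0.4,
                               ndvi = 0.3),
                 coef_sd = 0.25, lambda = 0.1, noise_sd = 0.3),
    observations = list(n = 300L),
    profiles = list(layers_per_profile = 5L),
    outliers = list(k = 1.5),
    screening = list(cor_threshold = 0.70, alpha = 0.05, priority = NULL),
    split = list(train_fraction = 0.75),
    gwr = list(kernel = "bisquare", k_min = NULL, k_max = NULL,
               ridge_jitter = 1e-8),
    scenario = list(decades = seq(2030L, 2100L, by = 10L),
                    temp_delta_per_decade = 0.3,
                    precip_factor_per_decade = 0.99,
                    perturbation_sd = 0),
    output_dir = NULL
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the [default_config()] defaults;
#' anything omitted keeps its default.
#'
#' @param path YAML file path.
#' @param seed Master seed used when the file does not set one.
#' @return A `run_config` list.
#' @export
read_config <- function(path, seed = 1L) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config(seed)), user)
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop_invalid("config must set a seed")
  with(cfg, {
    if (outliers$k <= 0) stop_invalid("outlier fence multiplier must be positive")
    if (screening$cor_threshold <= 0 || screening$cor_threshold > 1) {
      stop_invalid("cor_threshold must lie in (0, 1]")
    }
    if (screening$alpha <= 0 || screening$alpha >= 1) {
      stop_invalid("alpha must lie in (0, 1)")
    }
    if (split$train_fraction <= 0 || split$train_fraction >= 1) {
      stop_invalid("train_fraction must lie in (0, 1)")
    }
  })
  cfg
}
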