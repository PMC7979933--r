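#!/usr/bin/env Rscript
# Thin shell entry point over socgwr::run_pipeline().
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed <int>] --out <dir>

suppressMessages(library(socgwr))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
seed <- as.integer(get_arg("--seed", "1"))
cfg_path <- get_arg("--config")
out <- get_arg("--out")
if (is.null(out)) stop("--out <directory> is required", call. = FALSE)

cfg <- if (is.null(cfg_path)) default_config(seed) else read_config(cfg_path, seed)
if (!is.na(seed)) cfg$seed <- seed
art <- run_pipeline(cfg, out)
cat(sprintf("pipeline complete: %d observations, k = %s, test R2 = %.3f\n",
            nrow(art$observations), as.character(art$fit$k_selected),
            art$test_r2))
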