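#!/usr/bin/env Rscript
# Thin command-line wrapper over mindstate::run_pipeline().
#
#   Rscript scripts/mindstate.R --config cfg.yaml
#   Rscript scripts/mindstate.R --seed 3 --out runs/demo
#
# The YAML config accepts any pipeline_config() field; flags override it.

suppressMessages(library(mindstate))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}

cfg <- if (!is.null(get_arg("--config")))
  read_pipeline_config(get_arg("--config"))
else pipeline_config()
if (!is.null(get_arg("--seed"))) cfg$seed <- as.integer(get_arg("--seed"))
if (!is.null(get_arg("--out"))) cfg$out_dir <- get_arg("--out")

status <- tryCatch({
  run_pipeline(cfg)
  0L
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  1L
})
quit(status = status)
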