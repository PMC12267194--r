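#!/usr/bin/env Rscript
# Thin command-line wrapper over aortaflow::run_all(): runs the full study
# (generate -> ssm -> augment -> morpho -> select -> healthy sims -> ECMO
# subset -> ECMO sims -> report) with default parameters.
#
# Usage: Rscript scripts/run_pipeline.R --seed <int> --out <dir>
#        [--subjects N] [--k-healthy N] [--k-ecmo N] [--write-meshes]

suppressPackageStartupMessages(library(aortaflow))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out", "aortaflow-run")

config <- pipeline_config(
  out_dir = out_dir,
  seed = seed,
  population = population_spec(n_subjects = as.integer(get_arg("--subjects", "19"))),
  k_healthy = as.integer(get_arg("--k-healthy", "20")),
  k_ecmo = as.integer(get_arg("--k-ecmo", "4")),
  write_meshes = "--write-meshes" %in% args
)
manifest <- run_all(config)
print(manifest)
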