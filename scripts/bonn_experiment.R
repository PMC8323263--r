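#!/usr/bin/env Rscript
# External validation on the public Bonn EEG benchmark (requires a local
# download; the data are not redistributed and this script is not part of
# the test suite).
#
#   Rscript scripts/bonn_experiment.R --data <dir> [--task two_class]
#                                     [--epochs 512] [--seed 1]
#
# <dir> must contain one subdirectory per group (A-E or Z/O/N/F/S), each
# holding the 100 plain-text records of that group.

suppressPackageStartupMessages(library(rcnneeg))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

data_dir <- get_opt("--data")
if (is.null(data_dir)) {
  stop("usage: Rscript scripts/bonn_experiment.R --data <dir> [--task two_class]")
}
task <- get_opt("--task", "two_class")
epochs <- as.integer(get_opt("--epochs", "512"))
seed <- as.integer(get_opt("--seed", "1"))

report <- run_bonn_experiment(
  data_dir, task = task,
  config = train_config(epochs = epochs, seed = seed),
  seed = seed
)
print(report)
writeLines(metrics_table(stats::setNames(list(report), task)))
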