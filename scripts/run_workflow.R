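#!/usr/bin/env Rscript
# Thin command-line entry point for the analysis workflows.
#
# Usage: Rscript scripts/run_workflow.R <config.yaml> [out_dir]

suppressPackageStartupMessages(library(icmsans))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("usage: Rscript scripts/run_workflow.R <config.yaml> [out_dir]\n")
  quit(status = 2)
}
out_dir <- if (length(args) >= 2) args[2] else NULL
report <- run_workflow(args[1], out_dir = out_dir)
cat("workflow:", report$workflow, "done\n")
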