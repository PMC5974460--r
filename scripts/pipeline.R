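#!/usr/bin/env Rscript

# Thin shell entry point over needgap::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R --out <dir> [--seed <int>] [--profile MC|CSN]
#     [--conversations <int>] [--coverage <frac>] [--learner <name>]
#     [--stages synth,stats,rules,hasn,concepts,gap]
#
# Exit codes: 0 success, 2 configuration error, 4 stage failure.

suppressPackageStartupMessages(library(needgap))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = NULL, seed = 7L, profile = "MC", conversations = 40L,
            coverage = 0.5, learner = "random_forest",
            stages = c("synth", "stats", "rules", "hasn", "concepts", "gap"))
i <- 1L
ok <- TRUE
while (i <= length(args)) {
  key <- args[i]; val <- if (i < length(args)) args[i + 1L] else NA
  switch(key,
         "--out" = { opt$out <- val },
         "--seed" = { opt$seed <- as.integer(val) },
         "--profile" = { opt$profile <- val },
         "--conversations" = { opt$conversations <- as.integer(val) },
         "--coverage" = { opt$coverage <- as.numeric(val) },
         "--learner" = { opt$learner <- val },
         "--stages" = { opt$stages <- strsplit(val, ",")[[1]] },
         { message("unknown argument: ", key); ok <- FALSE })
  i <- i + 2L
}
if (!ok || is.null(opt$out)) {
  message("usage: Rscript scripts/pipeline.R --out <dir> [--seed <int>] ...")
  quit(status = 2L)
}

cfg <- tryCatch(
  pipeline_config(out_dir = opt$out, seed = opt$seed, profile = opt$profile,
                  n_conversations = opt$conversations,
                  coverage_fraction = opt$coverage, learner = opt$learner,
                  stages = opt$stages),
  error = function(e) { message("configuration error: ", conditionMessage(e)); NULL })
if (is.null(cfg)) quit(status = 2L)

res <- tryCatch({ run_pipeline(cfg); TRUE },
                error = function(e) { message("stage failure: ", conditionMessage(e)); FALSE })
quit(status = if (res) 0L else 4L)
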