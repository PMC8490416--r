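#!/usr/bin/env Rscript
# Writes the shared configuration for the analysis run. All later scripts
# read results/config.json, so editing the scale or seed here re-runs the
# whole chain consistently. Pass a master seed as the first argument
# (default 1).
suppressPackageStartupMessages(library(connevo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
cfg <- pipeline_config(n_surrogates = 500, n_permutations = 100,
                       seed = seed)
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(unclass(cfg), "results/config.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/config.json (master seed ", seed, ")")
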