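#!/usr/bin/env Rscript
# Generates the synthetic resting-state-like panel: modular node groups
# (planted segregators), weakly-but-broadly coupled hubs (planted
# integrators) and background noise nodes, one node-by-time matrix per
# subject. Writes per-subject TSVs plus the ground-truth labels.
suppressPackageStartupMessages(library(connevo))
cfg <- jsonlite::read_json("results/config.json", simplifyVector = TRUE)
modules <- split(seq_len(cfg$n_modules * cfg$module_size),
                 rep(seq_len(cfg$n_modules), each = cfg$module_size))
integrators <- cfg$n_modules * cfg$module_size + seq_len(cfg$n_integrators)
sp <- panel_spec(cfg$n_nodes, cfg$n_timepoints, modules,
                 cfg$module_coupling, cfg$coupling_spread, integrators,
                 cfg$integrator_coupling, cfg$noise_sd, cfg$n_subjects,
                 derive_seed(cfg$seed, "panel"))
panel <- gen_timeseries_panel(sp)
dir.create("results/panel", recursive = TRUE, showWarnings = FALSE)
for (s in seq_along(panel$panels))
  write_tsv_matrix(panel$panels[[s]],
                   sprintf("results/panel/subject_%02d.tsv", s),
                   id_col = "node")
write.table(data.frame(node = names(panel$labels), label = panel$labels),
            "results/panel/node_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(cfg$n_subjects, " subjects x ", cfg$n_nodes, " nodes written; ",
        sum(panel$labels == "segregator"), " segregators, ",
        sum(panel$labels == "integrator"), " integrators planted")
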