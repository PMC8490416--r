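#!/usr/bin/env Rscript
# Builds the per-subject functional graphs: pairwise Pearson correlation,
# Benjamini-Hochberg FDR thresholding at q (negative edges removed), and
# Fisher z-transformation. Writes one edge list per subject.
suppressPackageStartupMessages(library(connevo))
cfg <- jsonlite::read_json("results/config.json", simplifyVector = TRUE)
files <- sort(list.files("results/panel", "^subject_", full.names = TRUE))
if (!length(files)) stop("no panel found; run 01_simulate_panel.R first")
dir.create("results/graphs", showWarnings = FALSE)
for (f in files) {
  x <- read_tsv_matrix(f)
  g <- functional_graph(x, cfg$q_fdr)
  e <- edge_list(g$weights)
  out <- file.path("results/graphs",
                   sub("subject", "graph", basename(f)))
  write.table(format(e, digits = 17, trim = TRUE), out, sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(basename(f), ": ", nrow(e), " edges kept at q < ", cfg$q_fdr)
}
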