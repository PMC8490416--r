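# connevo

Functional-connectivity graph coarsening linked to cortical gene
expression and molecular evolution.

Resting-state functional MRI suggests that the human cortex balances two
organizational regimes: *segregation* (locally interconnected, specialized
modules) and *integration* (information flow across modules). `connevo`
implements a complete, testable pipeline around one way of quantifying
that balance and carrying it to evolutionary biology:

1. **Functional graphs.** Per subject, node-by-node Pearson correlation
   matrices with exact t-test p-values are thresholded by
   Benjamini–Hochberg FDR (default q < 0.001), negative edges are
   removed, and retained correlations are Fisher z-transformed.
2. **Merging-trajectory analysis.** Each graph is iteratively coarsened
   to its *minimal graph*: for an adjacent pair of super-nodes, the
   weighted degree of their shared links is compared with that of their
   distinct links, and the pair merges when shared > distinct, processing
   edges in descending weight order. Each node's cluster-size growth
   curve c_v(k) is fitted with a logarithmic model (early, concave
   mergers → *segregators*) and an exponential model (late, convex
   mergers → *integrators*); subject-normalized R² maps are averaged into
   group segregation (S), integration (I) and S−I phenotype maps.
3. **Transcriptome screen.** The S−I map is spatially correlated with a
   genes × regions expression matrix; genes beyond mean ± 1.96 SD of the
   correlation distribution form the upper/lower selections, and the
   cutoffs are certified against a pooled null built from
   spatial-autocorrelation-preserving surrogate maps (variogram-matched
   value permutations).
4. **Calibrated enrichment.** One-sided Fisher overrepresentation
   (hypergeometric upper tail) with term-size [5, 2000], minimum-overlap
   (3) and p < 0.01 prefilters; per-term empirical p-values calibrated
   against the surrogate-map gene selections; BH FDR; Cohen-kappa
   (> 0.3) term clustering with minimum-p representative terms.
5. **Evolution regression.** Per annotation, the mean dN/dS ratio across
   seven primate-human comparisons is regressed on divergence time under
   linear, logarithmic, quadratic and exponential families; the best
   model (smallest F-test p) is validated with a 100-list gene
   permutation null, z-scoring the observed R² against the null R²
   distribution (corrected p = 1 − Φ(z)).

A synthetic-data module (`panel_spec()`/`gen_timeseries_panel()`,
`gen_region_geometry()`, `gen_expression_matrix()`, `gen_gene_sets()`,
`gen_dnds_table()`) generates every input with planted ground truth, so
the full chain runs and is tested without any external data.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the default
synthetic world (200 nodes, 10 subjects, 2000 genes, 100 terms, 500
surrogates, 100 permutations) and write their tables under `results/`:

```sh
Rscript analysis/00_config.R 1      # master seed
Rscript analysis/01_simulate_panel.R
Rscript analysis/02_connectivity.R
Rscript analysis/03_merge_trajectories.R
Rscript analysis/04_gene_screen.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_evolution.R
```

With master seed 1 this prints, along the way:

```
10 subjects x 200 nodes written; 120 segregators, 8 integrators planted
group-level recovery vs planted labels: 0.891
selection cutoffs: -0.4579 / 0.4557; surrogate significance bounds: -0.2398 / 0.2398
52 upper-bound and 51 lower-bound genes selected; cutoffs beyond the spatial-autocorrelation null: TRUE
upper tail: 1 terms pass the prefilter, 1 survive FDR
  representative term(s): T001  (planted term recovered)
upper T001: best exponential (R2 = 0.995, F = 973.1), permutation-corrected p = 7.54e-06  [planted family: exponential]
```

Reading: 89% of the planted segregator/integrator nodes are recovered at
the group level; the ±1.96 SD selection cutoffs (±0.46) lie outside the
surrogate-null significance bounds (±0.24), so the selected genes are not
explainable by spatial autocorrelation; the planted annotation T001 is
the only FDR-surviving term and becomes its cluster's representative; and
its genes' mean dN/dS follows the planted exponential trend in divergence
time, surviving the gene-list permutation null.

Equivalently in one call:

```r
library(connevo)
res <- run_pipeline(pipeline_config(seed = 1))
```

## Acceptance script

`scripts/acceptance.R` re-runs the full synthetic pipeline from scratch
against the installed package and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All stage outputs land next to the report under
`results/pipeline_outputs/`, including the run manifest with per-stage
seeds and output checksums.
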