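#!/usr/bin/env Rscript
# Screens every gene's regional expression profile against the S-I
# phenotype map. Generates the synthetic expression matrix (planted
# genes at the target correlation plus spatially autocorrelated
# background), selects genes beyond +/- 1.96 SD of the correlation
# distribution, and certifies the cutoffs against the pooled null of
# variogram-matched surrogate maps.
suppressPackageStartupMessages(library(connevo))
cfg <- jsonlite::read_json("results/config.json", simplifyVector = TRUE)
rm_ <- read.delim("results/maps/region_map.tsv")
region_map <- setNames(rm_$S_minus_I, rm_$region)
geometry <- gen_region_geometry(cfg$n_regions, cfg$extent_mm,
                                derive_seed(cfg$seed, "geometry"))
region_map <- region_map[geometry$regions]
es <- expression_spec(cfg$n_genes, cfg$planted_pos, cfg$planted_neg,
                      cfg$target_abs_r, cfg$sa_length,
                      seed = derive_seed(cfg$seed, "expression"))
exprs <- gen_expression_matrix(region_map, geometry, es)
dir.create("results/screen", showWarnings = FALSE)
write_tsv_matrix(exprs$expr, "results/screen/expression.tsv",
                 id_col = "gene")
write.table(data.frame(region = rownames(geometry$coords),
                       geometry$coords),
            "results/screen/geometry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
screen <- gene_screen(region_map, exprs$expr, geometry,
                      cfg$sd_multiplier, cfg$n_surrogates,
                      derive_seed(cfg$seed, "surrogates"))
saveRDS(list(screen = screen, labels = exprs$labels,
             geometry = geometry, region_map = region_map),
        "results/screen/screen_state.rds")   # scratch for later stages
tail_of <- function(g) ifelse(g %in% screen$selection$upper, "upper",
                       ifelse(g %in% screen$selection$lower, "lower",
                              "none"))
write.table(format(data.frame(gene = names(screen$r),
                              r = as.vector(screen$r),
                              empirical_p = as.vector(screen$surrogate$p),
                              tail = tail_of(names(screen$r)),
                              truth = exprs$labels[names(screen$r)]),
                   digits = 17, trim = TRUE),
            "results/screen/gene_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("selection cutoffs: ",
        signif(screen$selection$lower_cutoff, 4), " / ",
        signif(screen$selection$upper_cutoff, 4),
        "; surrogate significance bounds: ",
        signif(screen$surrogate$lower_cutoff, 4), " / ",
        signif(screen$surrogate$upper_cutoff, 4))
message(length(screen$selection$upper), " upper-bound and ",
        length(screen$selection$lower), " lower-bound genes selected; ",
        "cutoffs beyond the spatial-autocorrelation null: ",
        screen$cutoffs_beyond_null)
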