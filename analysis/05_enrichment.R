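#!/usr/bin/env Rscript
# Surrogate-calibrated overrepresentation of the selected gene lists in
# a synthetic annotation collection with one planted term, followed by
# kappa-similarity clustering of the FDR-surviving terms.
suppressPackageStartupMessages(library(connevo))
cfg <- jsonlite::read_json("results/config.json", simplifyVector = TRUE)
st <- readRDS("results/screen/screen_state.rds")
screen <- st$screen
universe <- names(screen$r)
planted <- names(st$labels)[st$labels == "planted_pos"]
sets <- gen_gene_sets(universe, cfg$n_terms, cfg$term_size_range,
                      planted, derive_seed(cfg$seed, "gene_sets"))
dir.create("results/enrichment", showWarnings = FALSE)
write_gmt(sets$sets, "results/enrichment/gene_sets.gmt")
clusters <- list()
for (tail in c("upper", "lower")) {
  sel <- screen$selection[[tail]]
  cutoff <- screen$selection[[paste0(tail, "_cutoff")]]
  ssel <- surrogate_selections(screen$surrogate$null_r, cutoff, tail)
  res <- enrich_terms(sel, sets, ssel, cfg$enrich_q, cfg$term_size_min,
                      cfg$term_size_max, cfg$min_overlap, cfg$prefilter_p)
  write.table(format(res, digits = 17, trim = TRUE),
              sprintf("results/enrichment/enrichment_%s.tsv", tail),
              sep = "\t", quote = FALSE, row.names = FALSE)
  surv <- res$term[res$fdr_pass]
  message(tail, " tail: ", sum(res$prefilter_pass),
          " terms pass the prefilter, ", length(surv), " survive FDR")
  if (length(surv) >= 2) {
    km <- kappa_matrix(sets$sets[surv], universe)
    p <- setNames(res$empirical_p[match(surv, res$term)], surv)
    cl <- cluster_terms(km, p, cfg$kappa_threshold)
  } else if (length(surv) == 1) {
    cl <- data.frame(term = surv, cluster = 1L,
                     p = res$empirical_p[match(surv, res$term)],
                     representative = TRUE)
  } else cl <- NULL
  if (!is.null(cl)) {
    write.table(format(cl, digits = 17, trim = TRUE),
                sprintf("results/enrichment/clusters_%s.tsv", tail),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("  representative term(s): ",
            paste(cl$term[cl$representative], collapse = ", "),
            if (sets$planted_term %in% cl$term[cl$representative])
              "  (planted term recovered)" else "")
  }
  clusters[[tail]] <- cl
}
saveRDS(list(sets = sets, clusters = clusters),
        "results/enrichment/enrichment_state.rds")
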