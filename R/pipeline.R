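#' Configuration for the end-to-end synthetic pipeline
#'
#' Houses the analysis constants (FDR level for the connectivity graph,
#' the +/- 1.96 SD gene-selection multiplier, surrogate ensemble size,
#' kappa clustering threshold, term-size bounds, minimum overlap,
#' enrichment prefilter p, permutation count) together with the synthetic
#' world's scale. Every stochastic stage receives a sub-seed derived from
#' the master seed by stage-name hashing.
#'
#' @param n_nodes,n_timepoints,n_subjects panel dimensions.
#' @param n_modules,module_size,n_integrators planted structure: modules
#'   of segregator nodes plus weakly-but-broadly coupled integrator hubs;
#'   remaining nodes are background noise.
#' @param module_coupling,coupling_spread,integrator_coupling,noise_sd
#'   factor-model parameters (see [panel_spec()]).
#' @param n_regions,extent_mm region geometry for the expression stage.
#' @param n_genes,planted_pos,planted_neg,target_abs_r,sa_length
#'   expression-matrix parameters (see [expression_spec()]).
#' @param n_terms,term_size_range gene-set collection parameters.
#' @param q_fdr FDR level for connectivity-graph thresholding.
#' @param sd_multiplier gene-selection SD multiplier.
#' @param n_surrogates surrogate-map ensemble size.
#' @param enrich_q FDR level for calibrated enrichment.
#' @param kappa_threshold term-clustering kappa threshold.
#' @param term_size_min,term_size_max,min_overlap,prefilter_p enrichment
#'   filters.
#' @param n_permutations gene-list permutation count for the dN/dS
#'   regression null.
#' @param dnds_family,dnds_coefficients,dnds_noise_sd planted molecular
#'   evolution trend (see [dnds_spec()]).
#' @param seed master seed.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_nodes = 200, n_timepoints = 300,
                            n_subjects = 10,
                            n_modules = 4, module_size = 30,
                            n_integrators = 8,
                            module_coupling = 0.8, coupling_spread = 0.15,
                            integrator_coupling = 0.8, noise_sd = 0.5,
                            n_regions = 68, extent_mm = 140,
                            n_genes = 2000, planted_pos = 50,
                            planted_neg = 50, target_abs_r = 0.8,
                            sa_length = 25,
                            n_terms = 100, term_size_range = c(10, 200),
                            q_fdr = 0.001, sd_multiplier = 1.96,
                            n_surrogates = 1000, enrich_q = 0.05,
                            kappa_threshold = 0.3,
                            term_size_min = 5, term_size_max = 2000,
                            min_overlap = 3, prefilter_p = 0.01,
                            n_permutations = 100,
                            dnds_family = "exponential",
                            dnds_coefficients = c(0.12, 0.03),
                            dnds_noise_sd = 0.05,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (q_fdr <= 0 || q_fdr >= 1) stop("q_fdr must lie in (0, 1)")
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive")
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  if (kappa_threshold <= 0 || kappa_threshold >= 1)
    stop("kappa_threshold must lie in (0, 1)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (n_modules * module_size + n_integrators > n_nodes)
    stop("modules plus integrators exceed n_nodes")
  if (planted_pos + planted_neg > n_genes)
    stop("planted genes exceed n_genes")
  structure(cfg, class = "pipeline_config")
}

# Deterministic node -> region assignment (round-robin), standing in for
# the voxel-to-parcel mapping of real data.
node_regions <- function(n_nodes, n_regions) {
  paste0("r", ((seq_len(n_nodes) - 1L) %% n_regions) + 1L)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic world from the configuration, then executes all
#' stages: per-subject functional graphs, merging trajectories and
#' segregator/integrator classification; group S, I and S-I maps
#' aggregated onto regions; expression generation with planted genes and
#' the surrogate-calibrated gene screen; gene-set enrichment with kappa
#' clustering of surviving terms; and dN/dS curve fitting with the
#' permutation null for each representative term. If `out_dir` is given,
#' all stage outputs are written as TSV/GMT plus a JSON run manifest that
#' snapshots the configuration, per-stage seeds and output checksums
#' (sufficient to re-run bit-identically).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `truth` (generator ground truth), `maps`,
#'   `screen`, `enrichment` (per tail), `clusters`, `evolution`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seeds <- sapply(c("panel", "geometry", "expression", "gene_sets",
                    "surrogates", "dnds", "permutation"),
                  function(s) derive_seed(cfg$seed, s))

  # --- stage 1: synthetic panel ------------------------------------------
  modules <- split(seq_len(cfg$n_modules * cfg$module_size),
                   rep(seq_len(cfg$n_modules), each = cfg$module_size))
  integrators <- cfg$n_modules * cfg$module_size + seq_len(cfg$n_integrators)
  ps <- panel_spec(cfg$n_nodes, cfg$n_timepoints, modules,
                   cfg$module_coupling, cfg$coupling_spread, integrators,
                   cfg$integrator_coupling, cfg$noise_sd,
                   cfg$n_subjects, seeds[["panel"]])
  panel <- gen_timeseries_panel(ps)

  # --- stage 2-3: graphs, merging, classification ------------------------
  classifications <- lapply(panel$panels, function(x) {
    g <- functional_graph(x, cfg$q_fdr)
    fit_trajectory_models(run_merging(g))
  })
  maps <- group_maps(classifications)

  # --- stage 4: node map -> region phenotype map -------------------------
  nreg <- node_regions(cfg$n_nodes, cfg$n_regions)
  region_map <- tapply(maps$S_minus_I, nreg, mean)
  geometry <- gen_region_geometry(cfg$n_regions, cfg$extent_mm,
                                  seeds[["geometry"]])
  region_map <- region_map[geometry$regions]

  # --- stage 5: expression + gene screen ---------------------------------
  es <- expression_spec(cfg$n_genes, cfg$planted_pos, cfg$planted_neg,
                        cfg$target_abs_r, cfg$sa_length,
                        seed = seeds[["expression"]])
  exprs <- gen_expression_matrix(region_map, geometry, es)
  screen <- gene_screen(region_map, exprs$expr, geometry,
                        cfg$sd_multiplier, cfg$n_surrogates,
                        seeds[["surrogates"]])

  # --- stage 6: gene sets + calibrated enrichment ------------------------
  universe <- rownames(exprs$expr)
  planted_genes <- names(exprs$labels)[exprs$labels == "planted_pos"]
  sets <- gen_gene_sets(universe, cfg$n_terms, cfg$term_size_range,
                        planted_genes, seeds[["gene_sets"]])
  enr <- list()
  clusters <- list()
  for (tail in c("upper", "lower")) {
    sel <- screen$selection[[tail]]
    cutoff <- screen$selection[[paste0(tail, "_cutoff")]]
    ssel <- surrogate_selections(screen$surrogate$null_r, cutoff, tail)
    res <- enrich_terms(sel, sets, ssel, cfg$enrich_q,
                        cfg$term_size_min, cfg$term_size_max,
                        cfg$min_overlap, cfg$prefilter_p)
    enr[[tail]] <- res
    surv <- res$term[res$fdr_pass]
    clusters[[tail]] <- if (length(surv) >= 2) {
      km <- kappa_matrix(sets$sets[surv], universe)
      p <- stats::setNames(res$empirical_p[match(surv, res$term)], surv)
      cluster_terms(km, p, cfg$kappa_threshold)
    } else if (length(surv) == 1) {
      data.frame(term = surv, cluster = 1L,
                 p = res$empirical_p[match(surv, res$term)],
                 representative = TRUE, stringsAsFactors = FALSE)
    } else NULL
  }

  # --- stage 7: dN/dS curve fitting + permutation null -------------------
  ds <- dnds_spec(cfg$dnds_family, cfg$dnds_coefficients,
                  noise_sd = cfg$dnds_noise_sd, seed = seeds[["dnds"]])
  dn <- gen_dnds_table(ds, sets$sets[[sets$planted_term]], universe)
  ratios <- dnds_ratios(dn$table)
  times <- stats::setNames(dn$species$divergence_time_my,
                           dn$species$species)
  evolution <- list()
  for (tail in names(clusters)) {
    cl <- clusters[[tail]]
    if (is.null(cl)) next
    for (term in cl$term[cl$representative]) {
      gs <- sets$sets[[term]]
      mo <- annotation_species_means(ratios, gs)
      ft <- fit_curve_families(times, mo)
      pm <- permutation_corrected_p(ft, ratios, gs, universe,
                                    cfg$n_permutations,
                                    seeds[["permutation"]])
      evolution[[paste(tail, term, sep = ".")]] <-
        list(tail = tail, term = term, fit = ft, permutation = pm)
    }
  }

  manifest <- list(
    config = unclass(cfg),
    seeds = as.list(seeds),
    truth = list(planted_term = sets$planted_term,
                 dnds_family = ds$family,
                 n_planted_pos = cfg$planted_pos,
                 n_planted_neg = cfg$planted_neg))
  result <- list(truth = list(node_labels = panel$labels,
                              gene_labels = exprs$labels,
                              planted_term = sets$planted_term,
                              dnds = ds),
                 classifications = classifications,
                 maps = maps, region_map = region_map,
                 screen = screen, gene_sets = sets,
                 enrichment = enr, clusters = clusters,
                 evolution = evolution, manifest = manifest)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, cfg, out_dir)
    result$manifest$checksums <- manifest_checksums(out_dir)
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# Deterministic TSV/GMT dump of the main stage outputs.
write_pipeline_outputs <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.table(format(df, digits = 17, trim = TRUE),
                       file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  maps_df <- data.frame(node = names(result$maps$S),
                        S = result$maps$S, I = result$maps$I,
                        S_minus_I = result$maps$S_minus_I)
  wr(maps_df, "node_maps.tsv")
  wr(data.frame(region = names(result$region_map),
                S_minus_I = as.vector(result$region_map)),
     "region_map.tsv")
  wr(data.frame(gene = names(result$screen$r),
                r = as.vector(result$screen$r),
                p_empirical = as.vector(result$screen$surrogate$p),
                tail = ifelse(names(result$screen$r) %in%
                                result$screen$selection$upper, "upper",
                              ifelse(names(result$screen$r) %in%
                                       result$screen$selection$lower,
                                     "lower", "none"))),
     "gene_screen.tsv")
  for (tail in names(result$enrichment))
    wr(result$enrichment[[tail]], paste0("enrichment_", tail, ".tsv"))
  for (tail in names(result$clusters))
    if (!is.null(result$clusters[[tail]]))
      wr(result$clusters[[tail]], paste0("clusters_", tail, ".tsv"))
  if (length(result$evolution)) {
    ev <- do.call(rbind, lapply(result$evolution, function(e)
      data.frame(tail = e$tail, term = e$term, family = e$fit$best,
                 r2 = e$fit$fits$r2[match(e$fit$best, e$fit$fits$family)],
                 fstat = e$fit$fits$fstat[match(e$fit$best,
                                                e$fit$fits$family)],
                 p = e$fit$fits$p[match(e$fit$best, e$fit$fits$family)],
                 perm_z = e$permutation$z, perm_p = e$permutation$p)))
    wr(ev, "evolution.tsv")
  }
  write_gmt(result$gene_sets$sets, file.path(out_dir, "gene_sets.gmt"))
  invisible(out_dir)
}

manifest_checksums <- function(out_dir) {
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  stats::setNames(as.list(unname(sums)), basename(files))
}
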