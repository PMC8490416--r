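#' Specification for a synthetic resting-state-like time-series panel
#'
#' Describes a factor-model world: each module has one latent signal,
#' member nodes load on it with a common within-module coupling,
#' integrator hubs load weakly on the average of all module signals,
#' and every node receives independent Gaussian observation noise.
#' Only second-order structure (the correlation matrix) matters to the
#' downstream graph analysis, so a latent-factor model is sufficient.
#'
#' @param n_nodes total number of nodes.
#' @param n_timepoints number of time points per subject (>= 2).
#' @param modules list of integer vectors of node indices; each vector is
#'   one module. Memberships must be disjoint.
#' @param module_coupling mean loading of member nodes on their module
#'   signal, in `[0, 1]`. Either a scalar (shared by all modules) or one
#'   value per module.
#' @param coupling_spread half-width of the within-module loading
#'   gradient: member loadings are evenly spaced in
#'   `module_coupling +/- coupling_spread` and re-assigned to members at
#'   random in every subject. The gradient makes each module coarsen as a
#'   single chain (strongest pair first, then one member at a time) and
#'   the per-subject shuffle randomizes which members join late, which is
#'   what group averaging of the trajectory fits assumes.
#' @param integrator_nodes node indices coupled weakly-but-broadly to all
#'   modules (disjoint from module members).
#' @param integrator_coupling loading of an integrator node on the mean of
#'   the module signals, in `[0, 1]`.
#' @param noise_sd standard deviation of i.i.d. node noise (>= 0).
#' @param n_subjects number of independent subjects to generate.
#' @param seed integer seed; the generated panel is a pure function of the
#'   full specification including the seed.
#' @return an object of class `"panel_spec"`.
#' @export
panel_spec <- function(n_nodes, n_timepoints, modules,
                       module_coupling = 0.8,
                       coupling_spread = 0.15,
                       integrator_nodes = integer(0),
                       integrator_coupling = 0.8,
                       noise_sd = 0.5, n_subjects = 1L, seed = 1L) {
  stopifnot(n_nodes >= 1, n_timepoints >= 2, n_subjects >= 1)
  modules <- lapply(modules, as.integer)
  members <- unlist(modules)
  if (anyDuplicated(members))
    stop("module memberships must be disjoint")
  if (length(members) && (min(members) < 1 || max(members) > n_nodes))
    stop("module member indices out of range")
  integrator_nodes <- as.integer(integrator_nodes)
  if (any(integrator_nodes %in% members))
    stop("integrator nodes must not belong to a module")
  cpl <- rep_len(module_coupling, length(modules))
  if (any(cpl < 0 | cpl > 1) || integrator_coupling < 0 ||
      integrator_coupling > 1)
    stop("couplings must lie in [0, 1]")
  if (coupling_spread < 0 || any(cpl - coupling_spread < 0) ||
      any(cpl + coupling_spread > 1))
    stop("coupling_spread must keep all loadings in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(
    n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
    modules = modules, module_coupling = cpl,
    coupling_spread = coupling_spread,
    integrator_nodes = integrator_nodes,
    integrator_coupling = integrator_coupling,
    noise_sd = noise_sd, n_subjects = as.integer(n_subjects),
    seed = as.integer(seed)), class = "panel_spec")
}

#' Generate a panel of synthetic node-by-time matrices with ground truth
#'
#' Nodes belonging to a module are "segregator" ground truth (they share a
#' strong latent signal and merge early downstream); integrator hubs load
#' weakly on all module signals and merge late; remaining nodes are pure
#' noise background.
#'
#' @param spec a [panel_spec()].
#' @return list with `panels` (list of `n_nodes x n_timepoints` matrices,
#'   one per subject, rownames `"n<i>"`), `labels` (character vector:
#'   `"segregator"`, `"integrator"` or `"background"`), and `spec`.
#' @export
gen_timeseries_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_nodes
  tt <- spec$n_timepoints
  m <- length(spec$modules)
  labels <- rep("background", n)
  for (mod in spec$modules) labels[mod] <- "segregator"
  labels[spec$integrator_nodes] <- "integrator"
  node_ids <- paste0("n", seq_len(n))
  names(labels) <- node_ids
  set.seed(spec$seed)
  panels <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    f <- matrix(stats::rnorm(m * tt), m, tt)      # latent module signals
    # unit empirical variance so no module dominates the edge ordering
    f <- f / apply(f, 1, stats::sd)
    x <- matrix(0, n, tt)
    for (j in seq_along(spec$modules)) {
      mem <- spec$modules[[j]]
      loads <- seq(spec$module_coupling[j] + spec$coupling_spread,
                   spec$module_coupling[j] - spec$coupling_spread,
                   length.out = length(mem))
      loads <- sample(loads)             # shuffled gradient per subject
      x[mem, ] <- loads * matrix(f[j, ], length(mem), tt, byrow = TRUE)
    }
    if (length(spec$integrator_nodes) && m > 0) {
      fbar <- colMeans(f)                          # broad, weak coupling
      x[spec$integrator_nodes, ] <- rep(spec$integrator_coupling * fbar,
                                        each = length(spec$integrator_nodes))
    }
    x <- x + spec$noise_sd * matrix(stats::rnorm(n * tt), n, tt)
    rownames(x) <- node_ids
    panels[[s]] <- x
  }
  list(panels = panels, labels = labels, spec = spec)
}

#' Generate random region centroids and their distance matrix
#'
#' Centroids are drawn uniformly in a cube of side `extent_mm`; duplicated
#' centroids are re-drawn with a warning. Stands in for parcellation
#' centroid tables (e.g. a 68-region cortical atlas).
#'
#' @param n_regions number of regions (>= 2).
#' @param extent_mm side of the bounding cube in mm.
#' @param seed integer seed.
#' @return list with `regions` (ids), `coords` (`n x 3` matrix, mm) and
#'   `dist` (symmetric Euclidean distance matrix, mm).
#' @export
gen_region_geometry <- function(n_regions, extent_mm = 140, seed = 1L) {
  stopifnot(n_regions >= 2, extent_mm > 0)
  set.seed(seed)
  coords <- matrix(stats::runif(n_regions * 3, 0, extent_mm), n_regions, 3)
  for (tries in 1:100) {
    dup <- duplicated(coords)
    if (!any(dup)) break
    warning("duplicate centroids re-drawn")
    coords[dup, ] <- matrix(stats::runif(sum(dup) * 3, 0, extent_mm),
                            sum(dup), 3)
  }
  ids <- paste0("r", seq_len(n_regions))
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y", "z")
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(ids, ids)
  list(regions = ids, coords = coords, dist = d)
}

#' Specification for a synthetic genes-by-regions expression matrix
#'
#' @param n_genes total genes.
#' @param planted_pos,planted_neg number of genes constructed to correlate
#'   with the target map at `+target_abs_r` / `-target_abs_r`.
#' @param target_abs_r absolute planted correlation, in (0, 1).
#' @param spatial_autocorr_length Gaussian-kernel length scale (mm) used
#'   to smooth the background genes' white noise over the region geometry.
#' @param noise_sd standard deviation of residual expression noise.
#' @param seed integer seed.
#' @return an object of class `"expression_spec"`.
#' @export
expression_spec <- function(n_genes, planted_pos = 0L, planted_neg = 0L,
                            target_abs_r = 0.8,
                            spatial_autocorr_length = 25,
                            noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1, planted_pos >= 0, planted_neg >= 0,
            planted_pos + planted_neg <= n_genes,
            target_abs_r > 0, target_abs_r < 1,
            spatial_autocorr_length >= 0, noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 planted_pos = as.integer(planted_pos),
                 planted_neg = as.integer(planted_neg),
                 target_abs_r = target_abs_r,
                 spatial_autocorr_length = spatial_autocorr_length,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_spec")
}

# Row-normalized Gaussian smoothing kernel over a distance matrix.
# length_mm = 0 degenerates to the identity (no smoothing).
smoothing_kernel <- function(dist_mm, length_mm) {
  if (length_mm <= 0) return(diag(nrow(dist_mm)))
  k <- exp(-(dist_mm^2) / (2 * length_mm^2))
  k / rowSums(k)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Generate a synthetic expression matrix with planted gene-map correlations
#'
#' Background genes are spatially autocorrelated noise (white noise smoothed
#' with a Gaussian kernel over the centroid distance matrix). Each planted
#' gene is built as `r * z(map) + sqrt(1 - r^2) * z(e)`, where `e` is a
#' smoothed noise field orthogonalized against the map, so the in-sample
#' correlation with the target map equals the requested value exactly.
#' Expression is shifted to a positive mean level, which leaves all
#' correlations unchanged.
#'
#' @param target_map named numeric vector, one value per region of
#'   `geometry`; must be non-constant.
#' @param geometry a [gen_region_geometry()] result.
#' @param spec an [expression_spec()].
#' @return list with `expr` (genes x regions matrix), `labels` (character:
#'   `"planted_pos"`, `"planted_neg"`, `"background"`), and `spec`.
#' @export
gen_expression_matrix <- function(target_map, geometry, spec) {
  stopifnot(inherits(spec, "expression_spec"))
  regions <- geometry$regions
  if (!is.null(names(target_map))) target_map <- target_map[regions]
  if (length(target_map) != length(regions) || anyNA(target_map))
    stop("target_map must be defined on all regions of the geometry")
  if (stats::sd(target_map) == 0)
    stop("target_map is constant; planted correlation is undefined")
  nr <- length(regions)
  set.seed(spec$seed)
  kern <- smoothing_kernel(geometry$dist, spec$spatial_autocorr_length)
  zmap <- standardize(target_map)
  n <- spec$n_genes
  labels <- rep("background", n)
  if (spec$planted_pos) labels[seq_len(spec$planted_pos)] <- "planted_pos"
  if (spec$planted_neg)
    labels[spec$planted_pos + seq_len(spec$planted_neg)] <- "planted_neg"
  expr <- matrix(NA_real_, n, nr,
                 dimnames = list(paste0("g", seq_len(n)), regions))
  noise <- matrix(stats::rnorm(n * nr, sd = max(spec$noise_sd, 1)), n, nr)
  smooth <- noise %*% t(kern)
  r <- spec$target_abs_r
  for (i in seq_len(n)) {
    e <- smooth[i, ]
    if (labels[i] == "background") {
      expr[i, ] <- standardize(e)
    } else {
      eperp <- stats::residuals(stats::lm(e ~ zmap))
      g <- sign(1) * r * zmap + sqrt(1 - r^2) * standardize(eperp)
      if (labels[i] == "planted_neg") g <- -g
      expr[i, ] <- g
    }
  }
  expr <- expr + 5                    # expression-like positive level
  names(labels) <- rownames(expr)
  list(expr = expr, labels = labels, spec = spec)
}

#' Generate a GMT-style gene-set collection with one planted term
#'
#' One term consists exactly of `planted_term_genes`; the remaining terms
#' are drawn uniformly at random from the universe with sizes uniform in
#' `size_range`.
#'
#' @param gene_universe character vector of gene ids.
#' @param n_terms total number of terms (including the planted one if
#'   `planted_term_genes` is non-empty).
#' @param size_range integer length-2 vector of random-term sizes.
#' @param planted_term_genes character vector (subset of the universe), or
#'   `NULL` for a fully null collection.
#' @param seed integer seed.
#' @return list with `sets` (named list of gene-id vectors), `universe`,
#'   and `planted_term` (term id or `NA`).
#' @export
gen_gene_sets <- function(gene_universe, n_terms, size_range = c(10, 200),
                          planted_term_genes = NULL, seed = 1L) {
  stopifnot(n_terms >= 1, length(size_range) == 2)
  if (size_range[1] < 1 || size_range[2] > length(gene_universe))
    stop("size_range must lie within [1, |universe|]")
  if (!is.null(planted_term_genes) &&
      !all(planted_term_genes %in% gene_universe))
    stop("planted_term_genes must be a subset of the universe")
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  sets <- vector("list", n_terms)
  names(sets) <- ids
  planted_term <- NA_character_
  start <- 1L
  if (!is.null(planted_term_genes) && length(planted_term_genes)) {
    sets[[1L]] <- sort(unique(planted_term_genes))
    planted_term <- ids[1L]
    start <- 2L
  }
  if (start <= n_terms) {
    for (i in start:n_terms) {
      k <- sample(size_range[1]:size_range[2], 1L)
      sets[[i]] <- sort(sample(gene_universe, k))
    }
  }
  list(sets = sets, universe = gene_universe, planted_term = planted_term)
}

#' Specification for a synthetic dN/dS table
#'
#' The focal (trend) genes' dN/dS ratio follows one of four curve families
#' in divergence time plus per-gene Gaussian noise; all other universe
#' genes sit on a time-flat baseline plus the same noise, so that random
#' gene lists are null with respect to the trend. Default divergence times
#' are those of seven non-human primates versus human, in million years.
#'
#' @param family one of `"linear"`, `"logarithmic"`, `"quadratic"`,
#'   `"exponential"`.
#' @param coefficients numeric vector: `c(b0, b1)` (length 3 `c(b0,b1,b2)`
#'   for quadratic). Families: linear `b0 + b1*t`; logarithmic
#'   `b0 + b1*log(t)`; quadratic `b0 + b1*t + b2*t^2`; exponential
#'   `b0 * exp(b1*t)`.
#' @param times named numeric vector of divergence times (> 0, MY).
#' @param noise_sd per-gene Gaussian noise SD on the ratio scale.
#' @param baseline flat ratio for non-trend genes.
#' @param seed integer seed.
#' @return object of class `"dnds_spec"`.
#' @export
dnds_spec <- function(family = c("linear", "logarithmic", "quadratic",
                                 "exponential"),
                      coefficients = c(0.1, 0.002),
                      times = c(chimpanzee = 6.6, gorilla = 8.8,
                                orangutan = 15.8, macaque = 29.4,
                                olive_baboon = 29.4, vervet_AGM = 29.4,
                                marmoset = 43.2),
                      noise_sd = 0.02, baseline = 0.25, seed = 1L) {
  family <- match.arg(family)
  stopifnot(all(times > 0), noise_sd >= 0, baseline > 0)
  np <- if (family == "quadratic") 3L else 2L
  if (length(coefficients) != np)
    stop("wrong number of coefficients for family ", family)
  vals <- curve_family_value(family, coefficients, times)
  if (any(vals <= 0))
    stop("curve family takes non-positive values at the given times; ",
         "choose other coefficients")
  structure(list(family = family, coefficients = coefficients,
                 times = times, noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)), class = "dnds_spec")
}

# Evaluate one of the four curve families at times t.
curve_family_value <- function(family, b, t) {
  switch(family,
         linear = b[1] + b[2] * t,
         logarithmic = b[1] + b[2] * log(t),
         quadratic = b[1] + b[2] * t + b[3] * t^2,
         exponential = b[1] * exp(b[2] * t),
         stop("unknown family ", family))
}

#' Generate a long-format per-gene per-species dN/dS table
#'
#' For each gene-species pair, `dS` is drawn uniform on (0.05, 0.5) and
#' `dN = omega * dS`, where `omega` is the gene's target ratio (curve
#' family value for trend genes, flat baseline otherwise) plus Gaussian
#' noise; non-positive draws of `omega` are rejected and re-drawn so that
#' both `dN` and `dS` are strictly positive.
#'
#' @param spec a [dnds_spec()].
#' @param trend_genes character vector of genes that carry the planted
#'   time trend.
#' @param universe_genes character vector of all genes to tabulate
#'   (must contain `trend_genes`).
#' @return list with `table` (data.frame gene, species, dN, dS), `species`
#'   (data.frame species, divergence_time_my), and `spec`.
#' @export
gen_dnds_table <- function(spec, trend_genes, universe_genes) {
  stopifnot(inherits(spec, "dnds_spec"))
  if (!all(trend_genes %in% universe_genes))
    stop("trend_genes must be contained in universe_genes")
  set.seed(spec$seed)
  sp <- names(spec$times)
  vals <- curve_family_value(spec$family, spec$coefficients, spec$times)
  ng <- length(universe_genes)
  ns <- length(sp)
  target <- matrix(spec$baseline, ng, ns,
                   dimnames = list(universe_genes, sp))
  if (length(trend_genes))
    target[trend_genes, ] <- matrix(vals, length(trend_genes), ns,
                                    byrow = TRUE)
  omega <- target + matrix(stats::rnorm(ng * ns, sd = spec$noise_sd), ng, ns)
  bad <- which(omega <= 0)
  for (tries in 1:1000) {            # rejection keeps ratios positive
    if (!length(bad)) break
    omega[bad] <- target[bad] + stats::rnorm(length(bad), sd = spec$noise_sd)
    bad <- bad[omega[bad] <= 0]
  }
  if (length(bad))
    stop("could not draw positive dN/dS ratios; lower noise_sd")
  ds <- matrix(stats::runif(ng * ns, 0.05, 0.5), ng, ns)
  tab <- data.frame(
    gene = rep(universe_genes, times = ns),
    species = rep(sp, each = ng),
    dN = as.vector(omega * ds),
    dS = as.vector(ds),
    stringsAsFactors = FALSE)
  list(table = tab,
       species = data.frame(species = sp,
                            divergence_time_my = unname(spec$times),
                            stringsAsFactors = FALSE),
       spec = spec)
}

#' Canonical true-coefficient sets for the four dN/dS curve families
#'
#' Shapes chosen to be mutually distinguishable at the default divergence
#' times under moderate noise: a steep low-intercept line, a saturating
#' logarithm, a U-shaped quadratic and a clearly convex exponential, all
#' strictly positive over the default time range.
#'
#' @param family curve family name.
#' @return numeric coefficient vector for [dnds_spec()].
#' @export
default_dnds_coefficients <- function(family = c("linear", "logarithmic",
                                                 "quadratic",
                                                 "exponential")) {
  switch(match.arg(family),
         linear = c(0.02, 0.006),
         logarithmic = c(0.05, 0.03),
         quadratic = c(0.3, -0.015, 4e-4),
         exponential = c(0.12, 0.03))
}
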