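#' Size-filter a gene-set collection
#'
#' Removes terms with fewer than `min_size` or more than `max_size` genes
#' (bounds follow common ontology practice: "less than 5" and "more than
#' 2000" are exclusive, so sizes 5 and 2000 are kept).
#'
#' @param collection list with `sets` (named list of gene vectors) and
#'   `universe`.
#' @param min_size,max_size inclusive size bounds.
#' @return the collection with undersized/oversized terms dropped;
#'   attribute `removed` lists the dropped term ids.
#' @export
filter_terms <- function(collection, min_size = 5, max_size = 2000) {
  if (!length(collection$universe)) stop("empty gene universe")
  sizes <- lengths(collection$sets)
  keep <- sizes >= min_size & sizes <= max_size
  out <- collection
  out$sets <- collection$sets[keep]
  attr(out, "removed") <- names(collection$sets)[!keep]
  out
}

#' One-sided Fisher overrepresentation test with fold enrichment
#'
#' One-sided (greater) Fisher exact p-value for the 2x2 table of
#' in/out-selection by in/out-term membership; identical to the
#' hypergeometric upper tail `P(X >= overlap)`. Fold enrichment is the
#' observed overlap fraction over its expectation,
#' `(overlap/|selection|) / (|term|/|universe|)`.
#'
#' @param selection character vector of selected genes.
#' @param term character vector of term member genes.
#' @param universe character vector of all genes.
#' @return list with `p`, `fold`, `overlap`.
#' @export
fisher_overrepresentation <- function(selection, term, universe) {
  if (!length(selection)) stop("empty selection")
  selection <- intersect(selection, universe)
  term <- intersect(term, universe)
  ov <- length(intersect(selection, term))
  N <- length(universe)
  p <- stats::phyper(ov - 1, length(term), N - length(term),
                     length(selection), lower.tail = FALSE)
  fold <- (ov / length(selection)) / (length(term) / N)
  list(p = p, fold = fold, overlap = ov)
}

# Vectorized hypergeometric upper-tail p-values and folds for a
# term-membership indicator matrix (terms x genes) against one or more
# selection indicator vectors (genes x selections).
overrep_matrix <- function(term_mat, sel_mat, N) {
  ov <- term_mat %*% sel_mat                    # terms x selections
  ksz <- rowSums(term_mat)
  ssz <- colSums(sel_mat)
  K <- matrix(ksz, nrow(ov), ncol(ov))
  S <- matrix(ssz, nrow(ov), ncol(ov), byrow = TRUE)
  p <- stats::phyper(ov - 1, K, N - K, S, lower.tail = FALSE)
  fold <- (ov / S) / (K / N)
  list(p = p, fold = fold, overlap = ov)
}

#' Surrogate-calibrated empirical p-value for one term
#'
#' Compares a term's observed Fisher p-value with the Fisher p-values the
#' same term attains on the surrogate-map gene selections:
#' `p_emp = (1 + #{p_surrogate < p_observed} + B) / (S + 1)`, where `B`
#' splits the surrogate p-values tied with the observed one. With
#' `tie_break = "random"` (default) `B` is drawn uniformly on
#' `0..#ties`, which makes the empirical p exactly uniform under
#' exchangeability despite the heavy discreteness of Fisher p-values on
#' small tables; `"conservative"` uses `B = #ties` (every tie counts
#' against the observation, the classical conservative convention).
#'
#' @param original_p observed Fisher p for the term.
#' @param surrogate_p numeric vector of the term's Fisher p-values on the
#'   surrogate selections.
#' @param tie_break `"random"` or `"conservative"`.
#' @return empirical p-value in `[1/(S+1), 1]`.
#' @export
surrogate_calibrated_p <- function(original_p, surrogate_p,
                                   tie_break = c("random", "conservative")) {
  tie_break <- match.arg(tie_break)
  if (!length(surrogate_p)) stop("need at least one surrogate selection")
  lt <- sum(surrogate_p < original_p)
  ties <- sum(surrogate_p == original_p)
  b <- if (tie_break == "random") sample.int(ties + 1L, 1L) - 1L else ties
  (1 + lt + b) / (length(surrogate_p) + 1)
}

#' Surrogate-calibrated overrepresentation analysis of a gene selection
#'
#' For every term that passes the size filter: the one-sided Fisher p and
#' fold enrichment of the observed selection; the empirical p calibrated
#' against the surrogate selections; prefilter flags (overlap below
#' `min_overlap`, or Fisher p at or above `prefilter_p`, mark a term for
#' discard after testing); and Benjamini-Hochberg FDR of the empirical
#' p-values across the prefilter-passing terms.
#'
#' @param selection character vector of selected genes.
#' @param collection gene-set collection (list with `sets`, `universe`).
#' @param surrogate_sel list of surrogate gene selections (character
#'   vectors), e.g. from [surrogate_selections()].
#' @param q FDR level for the empirical p-values.
#' @param min_size,max_size term size bounds for [filter_terms()].
#' @param min_overlap minimum selection-term overlap (prefilter).
#' @param prefilter_p uncorrected Fisher-p prefilter threshold.
#' @param tie_break tie handling for the empirical p (see
#'   [surrogate_calibrated_p()]); the random splitting is seeded by
#'   `seed` so results are reproducible.
#' @param seed integer seed for the randomized tie splitting.
#' @return data.frame, one row per size-passing term: `term`, `size`,
#'   `overlap`, `fold`, `p`, `empirical_p`, `fdr_p` (NA for prefiltered
#'   terms), `prefilter_pass`, `fdr_pass`.
#' @export
enrich_terms <- function(selection, collection, surrogate_sel,
                         q = 0.05, min_size = 5, max_size = 2000,
                         min_overlap = 3, prefilter_p = 0.01,
                         tie_break = c("random", "conservative"),
                         seed = 1L) {
  tie_break <- match.arg(tie_break)
  coll <- filter_terms(collection, min_size, max_size)
  if (!length(coll$sets))
    return(data.frame(term = character(0)))
  universe <- coll$universe
  N <- length(universe)
  term_mat <- do.call(rbind, lapply(coll$sets, function(g)
    as.numeric(universe %in% g)))
  sel_all <- c(list(selection), surrogate_sel)
  sel_mat <- sapply(sel_all, function(g) as.numeric(universe %in% g))
  ores <- overrep_matrix(term_mat, sel_mat, N)
  S <- length(surrogate_sel)
  obs_p <- ores$p[, 1]
  emp_p <- if (S > 0) {
    obs_mat <- matrix(obs_p, nrow(ores$p), S)
    lt <- rowSums(ores$p[, -1, drop = FALSE] < obs_mat)
    ties <- rowSums(ores$p[, -1, drop = FALSE] == obs_mat)
    b <- if (tie_break == "random") {
      set.seed(seed)
      vapply(ties, function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
    } else ties
    (1 + lt + b) / (S + 1)
  } else rep(NA_real_, length(obs_p))
  res <- data.frame(term = names(coll$sets),
                    size = rowSums(term_mat),
                    overlap = ores$overlap[, 1],
                    fold = ores$fold[, 1],
                    p = obs_p,
                    empirical_p = emp_p,
                    stringsAsFactors = FALSE)
  res$prefilter_pass <- res$overlap >= min_overlap & res$p < prefilter_p
  res$fdr_p <- NA_real_
  if (any(res$prefilter_pass) && S > 0) {
    res$fdr_p[res$prefilter_pass] <-
      stats::p.adjust(res$empirical_p[res$prefilter_pass], method = "BH")
  }
  res$fdr_pass <- !is.na(res$fdr_p) & res$fdr_p <= q
  rownames(res) <- NULL
  res
}

#' Cohen's kappa similarity matrix between terms
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between
#' the binary gene-membership vectors of every term pair over the
#' universe. A pair with `p_e = 1` (both terms equal to the universe) has
#' undefined kappa and is set to 0 with a flag in the `undefined`
#' attribute.
#'
#' @param sets named list (>= 2) of term gene vectors.
#' @param universe character vector of all genes.
#' @return symmetric kappa matrix with unit diagonal.
#' @export
kappa_matrix <- function(sets, universe) {
  stopifnot(length(sets) >= 2)
  N <- length(universe)
  m <- do.call(rbind, lapply(sets, function(g) universe %in% g))
  k <- matrix(1, length(sets), length(sets),
              dimnames = list(names(sets), names(sets)))
  undef <- matrix(FALSE, length(sets), length(sets))
  for (a in seq_len(length(sets) - 1)) {
    for (b in (a + 1):length(sets)) {
      x <- m[a, ]; y <- m[b, ]
      po <- mean(x == y)
      py1 <- mean(x); py2 <- mean(y)
      pe <- py1 * py2 + (1 - py1) * (1 - py2)
      if (pe >= 1) {
        k[a, b] <- k[b, a] <- 0
        undef[a, b] <- undef[b, a] <- TRUE
      } else {
        k[a, b] <- k[b, a] <- (po - pe) / (1 - pe)
      }
    }
  }
  attr(k, "undefined") <- undef
  k
}

#' Cluster terms by kappa similarity and pick representative terms
#'
#' Average-linkage hierarchical clustering on the distance `1 - kappa`,
#' cut at height `1 - kappa_threshold` so that merged clusters have
#' average pairwise kappa above the threshold. Each cluster's
#' representative is its member with the smallest p-value (ties broken by
#' term id order); singletons are reported as their own clusters.
#'
#' @param kappa symmetric kappa matrix (e.g. [kappa_matrix()]).
#' @param p named numeric vector of per-term p-values (empirical p from
#'   [enrich_terms()]); names must match the kappa matrix.
#' @param kappa_threshold clustering threshold (default 0.3).
#' @return data.frame with `term`, `cluster`, `p`, `representative`.
#' @export
cluster_terms <- function(kappa, p, kappa_threshold = 0.3) {
  terms <- rownames(kappa)
  stopifnot(!is.null(terms), all(terms %in% names(p)))
  p <- p[terms]
  if (length(terms) == 1) {
    return(data.frame(term = terms, cluster = 1L, p = unname(p),
                      representative = TRUE, stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(stats::as.dist(1 - kappa), method = "average")
  cl <- stats::cutree(hc, h = 1 - kappa_threshold)
  rep_flag <- logical(length(terms))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    best <- idx[order(p[idx], terms[idx])][1]
    rep_flag[best] <- TRUE
  }
  data.frame(term = terms, cluster = as.integer(cl), p = unname(p),
             representative = rep_flag, stringsAsFactors = FALSE)
}
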