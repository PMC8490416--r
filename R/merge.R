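#' Shared-versus-distinct merge decision for one adjacent pair
#'
#' For adjacent super-nodes `u` and `v`, the shared weighted degree is the
#' sum, over neighbors adjacent to both, of both incident weights
#' `w(u, x) + w(v, x)`; the distinct weighted degree is the sum, over
#' neighbors adjacent to exactly one of the pair, of that single weight.
#' The `(u, v)` edge itself contributes to neither sum. The pair merges
#' iff the shared degree strictly exceeds the distinct degree.
#'
#' @param w symmetric nonnegative weight matrix of the current
#'   (possibly coarsened) graph; 0 encodes "no edge".
#' @param u,v indices of two adjacent super-nodes.
#' @return list with `merge` (logical), `shared`, `distinct`.
#' @export
evaluate_pair <- function(w, u, v) {
  if (u == v) stop("u and v must differ")
  if (w[u, v] <= 0) stop("pair (", u, ",", v, ") is not adjacent")
  wu <- w[u, ]
  wv <- w[v, ]
  wu[c(u, v)] <- 0
  wv[c(u, v)] <- 0
  both <- wu > 0 & wv > 0
  shared <- sum(wu[both]) + sum(wv[both])
  distinct <- sum(wu[!both]) + sum(wv[!both])
  list(merge = shared > distinct, shared = shared, distinct = distinct)
}

#' Coarsen a weighted graph to its minimal graph by iterative merging
#'
#' Repeats passes over the live edges sorted by descending weight (ties
#' broken by the lexicographic (min id, max id) order of the incident
#' super-node slots). Each edge whose endpoints are still untouched this
#' pass is submitted to [evaluate_pair()]; on a merge, the absorbing
#' super-node keeps the smaller slot index and its weight to any neighbor
#' becomes the mean over all original member pairs of the original
#' weights, counting absent original links as zero (size-weighted average
#' of the two rows). A merged node's new edges enter consideration at the
#' next pass. Passes repeat until a full pass produces no merge.
#'
#' @param graph a weighted graph (list with `weights` matrix and `nodes`),
#'   e.g. from [functional_graph()], or a plain symmetric matrix.
#' @return an object of class `"merge_trajectory"`: list with
#'   \describe{
#'     \item{events}{data.frame (k, a, b, new_size): at event k, slot b was
#'       absorbed into slot a, whose super-node then had `new_size`
#'       original members.}
#'     \item{growth}{n x K matrix; `growth[v, k]` is the size of node v's
#'       super-node after event k (`c_v(k)`, non-decreasing, `c_v(0) = 1`).}
#'     \item{members}{list of member index sets of the live super-nodes of
#'       the minimal graph.}
#'     \item{minimal}{weight matrix of the minimal graph (live slots).}
#'     \item{nodes}{original node ids; `n_nodes`, `K`.}
#'   }
#' @export
run_merging <- function(graph) {
  w <- if (is.list(graph)) graph$weights else graph
  nodes <- if (is.list(graph) && !is.null(graph$nodes)) graph$nodes
           else rownames(w)
  n <- nrow(w)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  merge_engine(w, nodes, rule = "shared_distinct")
}

#' Random-rule merging baseline
#'
#' Same bookkeeping as [run_merging()] but, instead of the
#' shared-versus-distinct rule applied in descending weight order, a live
#' edge is chosen uniformly at random and its endpoints merged
#' unconditionally, until one super-node per connected component remains.
#' Used only for comparison reports of cumulative merged-link counts.
#'
#' @inheritParams run_merging
#' @param seed integer seed making the trajectory deterministic.
#' @return a `"merge_trajectory"` object.
#' @export
random_rule_baseline <- function(graph, seed = 1L) {
  w <- if (is.list(graph)) graph$weights else graph
  nodes <- if (is.list(graph) && !is.null(graph$nodes)) graph$nodes
           else rownames(w)
  n <- nrow(w)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  set.seed(seed)
  merge_engine(w, nodes, rule = "random")
}

# Shared engine for both merging rules. Weights between super-nodes are
# maintained incrementally as size-weighted row averages, which equals the
# mean over all original member pairs with absent links counted as zero.
merge_engine <- function(w, nodes, rule) {
  n <- nrow(w)
  stopifnot(isTRUE(all.equal(w, t(w), check.attributes = FALSE)),
            all(w >= 0))
  diag(w) <- 0
  alive <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  ev_k <- integer(0); ev_a <- integer(0); ev_b <- integer(0)
  ev_size <- integer(0)
  growth_cols <- list()
  cur <- rep(1L, n)
  k <- 0L

  do_merge <- function(u, v) {
    a <- min(u, v); b <- max(u, v)
    new_row <- (size[a] * w[a, ] + size[b] * w[b, ]) / (size[a] + size[b])
    new_row[c(a, b)] <- 0
    w[a, ] <<- new_row
    w[, a] <<- new_row
    w[b, ] <<- 0
    w[, b] <<- 0
    size[a] <<- size[a] + size[b]
    members[[a]] <<- c(members[[a]], members[[b]])
    members[[b]] <<- integer(0)
    alive[b] <<- FALSE
    k <<- k + 1L
    cur[members[[a]]] <<- size[a]
    ev_k[k] <<- k; ev_a[k] <<- a; ev_b[k] <<- b; ev_size[k] <<- size[a]
    growth_cols[[k]] <<- cur
  }

  if (rule == "shared_distinct") {
    repeat {
      idx <- which(upper.tri(w) & w > 0)
      if (!length(idx)) break
      i <- ((idx - 1L) %% n) + 1L
      j <- ((idx - 1L) %/% n) + 1L
      ord <- order(-w[idx], i, j)
      merged_any <- FALSE
      for (e in ord) {
        u <- i[e]; v <- j[e]
        # an absorbed endpoint kills its queued edges; edges of the
        # surviving super-node stay in this pass's schedule and are
        # evaluated against the current coarsened state
        if (!alive[u] || !alive[v] || w[u, v] <= 0) next
        dec <- evaluate_pair(w, u, v)
        if (dec$merge) {
          do_merge(u, v)
          merged_any <- TRUE
        }
      }
      if (!merged_any) break
    }
  } else if (rule == "random") {
    repeat {
      idx <- which(upper.tri(w) & w > 0)
      if (!length(idx)) break
      e <- if (length(idx) == 1L) idx else sample(idx, 1L)
      u <- ((e - 1L) %% n) + 1L
      v <- ((e - 1L) %/% n) + 1L
      do_merge(u, v)
    }
  } else stop("unknown rule")

  growth <- if (k > 0) do.call(cbind, growth_cols)
            else matrix(integer(0), n, 0)
  rownames(growth) <- nodes
  live <- which(alive)
  structure(list(
    events = data.frame(k = ev_k, a = ev_a, b = ev_b, new_size = ev_size),
    growth = growth,
    members = members[live],
    minimal = w[live, live, drop = FALSE],
    nodes = nodes, n_nodes = n, K = k), class = "merge_trajectory")
}

#' Classify nodes as segregators or integrators from their growth curves
#'
#' For each original node, the normalized growth curve `y_k = c_v(k)/n`
#' against normalized event time `t_k = k/K` is fitted with a logarithmic
#' model `y = a + b*log(t + eps)` and an exponential model
#' `y = a*exp(b*t)` (by ordinary least squares on `log y`). R-squared is
#' evaluated on the original `y` scale for both models and clamped to
#' `[0, 1]`. A node with the higher logarithmic R-squared (early, concave
#' growth) is a segregator; higher exponential R-squared (late, convex
#' growth) marks an integrator; ties and never-merging nodes are
#' unclassified.
#'
#' @param traj a `"merge_trajectory"` from [run_merging()].
#' @param eps saturation offset of the logarithmic model (default 0.2).
#'   A fixed offset keeps the regressor's curvature moderate and
#'   independent of the number of merge events; an offset shrinking with
#'   `1/K` would let the first events dominate the fit.
#' @return data.frame with one row per node: `node`, `r2_log`, `r2_exp`,
#'   fitted coefficients, `score` (`r2_log - r2_exp`), `label`.
#' @export
fit_trajectory_models <- function(traj, eps = 0.2) {
  stopifnot(inherits(traj, "merge_trajectory"))
  K <- traj$K
  if (K < 3) stop("need at least 3 merge events to fit trajectory models")
  n <- traj$n_nodes
  t <- seq_len(K) / K
  lt <- log(t + eps)
  res <- data.frame(node = traj$nodes,
                    r2_log = NA_real_, r2_exp = NA_real_,
                    a_log = NA_real_, b_log = NA_real_,
                    a_exp = NA_real_, b_exp = NA_real_,
                    score = NA_real_, label = "unclassified",
                    stringsAsFactors = FALSE)
  for (v in seq_len(n)) {
    y <- traj$growth[v, ] / n
    if (stats::sd(y) == 0) next               # never merges: flagged
    sst <- sum((y - mean(y))^2)
    flog <- stats::lm.fit(cbind(1, lt), y)
    r2l <- max(0, min(1, 1 - sum(flog$residuals^2) / sst))
    if (all(y > 0)) {              # growth curves are positive by design
      fexp <- stats::lm.fit(cbind(1, t), log(y))
      pred <- exp(fexp$coefficients[1] + fexp$coefficients[2] * t)
      r2e <- max(0, min(1, 1 - sum((y - pred)^2) / sst))
    } else {
      fexp <- list(coefficients = c(NA_real_, NA_real_))
      r2e <- 0
    }
    s <- r2l - r2e
    res$r2_log[v] <- r2l; res$r2_exp[v] <- r2e
    res$a_log[v] <- flog$coefficients[1]; res$b_log[v] <- flog$coefficients[2]
    res$a_exp[v] <- exp(fexp$coefficients[1]); res$b_exp[v] <- fexp$coefficients[2]
    res$score[v] <- s
    res$label[v] <- if (s > 0) "segregator"
                    else if (s < 0) "integrator" else "unclassified"
  }
  res
}

# Min-max normalization to [0, 1]; a constant vector maps to zeros.
minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Group-level segregation, integration and S-I phenotype maps
#'
#' Per subject, the R-squared maps of the logarithmic and exponential fits
#' are min-max normalized to `[0, 1]`; the group segregation (S) and
#' integration (I) maps are their element-wise means across subjects, and
#' the phenotype map is their subtraction S - I. Nodes unclassified in a
#' subject (never merged) contribute 0 for that subject.
#'
#' @param classifications list of per-subject data.frames from
#'   [fit_trajectory_models()]; all must share the same node ids in the
#'   same order.
#' @return list of three named numeric vectors: `S`, `I`, `S_minus_I`.
#' @export
group_maps <- function(classifications) {
  stopifnot(length(classifications) >= 1)
  nodes <- classifications[[1]]$node
  for (cl in classifications)
    if (!identical(cl$node, nodes)) stop("subjects must share node ids")
  smat <- sapply(classifications, function(cl)
    minmax(ifelse(is.na(cl$r2_log), 0, cl$r2_log)))
  imat <- sapply(classifications, function(cl)
    minmax(ifelse(is.na(cl$r2_exp), 0, cl$r2_exp)))
  S <- rowMeans(smat)
  I <- rowMeans(imat)
  names(S) <- names(I) <- nodes
  list(S = S, I = I, S_minus_I = S - I)
}


#' Group-level node labels from per-subject trajectory fits
#'
#' Averages the per-subject segregation scores (`r2_log - r2_exp`) across
#' subjects (a node unclassified in a subject contributes 0) and labels
#' each node by the sign of the mean score. Averaging across subjects is
#' what makes the classification robust: within one subject the absorption
#' order inside a module is arbitrary, so individual late-joining members
#' can look integrator-like, but their expected score across subjects is
#' positive.
#'
#' @inheritParams group_maps
#' @return data.frame with `node`, `score` (subject-mean), `label`.
#' @export
group_classification <- function(classifications) {
  stopifnot(length(classifications) >= 1)
  nodes <- classifications[[1]]$node
  sc <- rowMeans(sapply(classifications, function(cl)
    ifelse(is.na(cl$score), 0, cl$score)))
  data.frame(node = nodes, score = sc,
             label = ifelse(sc > 0, "segregator",
                            ifelse(sc < 0, "integrator", "unclassified")),
             stringsAsFactors = FALSE)
}
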