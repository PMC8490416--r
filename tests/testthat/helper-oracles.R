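# Independent reference implementations used as oracles. These are kept
# deliberately naive: every quantity is recomputed from scratch at every
# step, with no incremental state.

# Brute-force reference for the merging algorithm. Groups are member
# index sets; the weight between two groups is recomputed from the
# original matrix each time as the mean over all member pairs (absent
# links count 0). Pass schedule mirrors the documented semantics: edges
# sorted by descending pass-start weight (ties by slot ids), an edge is
# skipped when an endpoint group has died, and decisions use the current
# membership state.
ref_merging <- function(w0) {
  n <- nrow(w0)
  members <- lapply(seq_len(n), identity)
  alive <- rep(TRUE, n)
  gw <- function(a, b) {
    sum(w0[members[[a]], members[[b]]]) /
      (length(members[[a]]) * length(members[[b]]))
  }
  events <- list()
  k <- 0
  repeat {
    live <- which(alive)
    pairs <- NULL
    for (a in live) for (b in live) if (a < b) {
      w <- gw(a, b)
      if (w > 0) pairs <- rbind(pairs, c(a, b, w))
    }
    if (is.null(pairs)) break
    pairs <- pairs[order(-pairs[, 3], pairs[, 1], pairs[, 2]), ,
                   drop = FALSE]
    merged_any <- FALSE
    for (e in seq_len(nrow(pairs))) {
      a <- pairs[e, 1]; b <- pairs[e, 2]
      if (!alive[a] || !alive[b]) next
      if (gw(a, b) <= 0) next
      shared <- 0; distinct <- 0
      for (c in which(alive)) {
        if (c == a || c == b) next
        wac <- gw(a, c); wbc <- gw(b, c)
        if (wac > 0 && wbc > 0) shared <- shared + wac + wbc
        else if (wac > 0) distinct <- distinct + wac
        else if (wbc > 0) distinct <- distinct + wbc
      }
      if (shared > distinct) {
        keep <- min(a, b); drop <- max(a, b)
        members[[keep]] <- c(members[[keep]], members[[drop]])
        members[[drop]] <- integer(0)
        alive[drop] <- FALSE
        k <- k + 1
        events[[k]] <- c(k = k, a = keep, b = drop,
                         new_size = length(members[[keep]]))
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  if (k == 0) return(data.frame(k = integer(0), a = integer(0),
                                b = integer(0), new_size = integer(0)))
  as.data.frame(do.call(rbind, events))
}

# Brute-force Benjamini-Hochberg: largest k with p(k) <= k q / m.
ref_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[p <= ps[max(k)]] <- TRUE
  rej
}

# Hypergeometric upper tail by direct enumeration.
ref_hyper_upper <- function(ov, K, N, s) {
  ks <- ov:min(K, s)
  sum(choose(K, ks) * choose(N - K, s - ks)) / choose(N, s)
}

# Random connected weighted graph with distinct weights.
random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- stats::runif(length(ut)) < p_edge
    w[ut[on]] <- stats::runif(sum(on), 0.05, 1)
    w <- w + t(w)
    # connectivity via reachability
    reach <- rep(FALSE, n); reach[1] <- TRUE
    repeat {
      new <- reach | (colSums(w[reach, , drop = FALSE] > 0) > 0)
      if (all(new == reach)) break
      reach <- new
    }
    if (all(reach) && !anyDuplicated(w[upper.tri(w)][w[upper.tri(w)] > 0]))
      return(w)
  }
}

# Spatially autocorrelated Gaussian map on a geometry.
sa_map <- function(geometry, length_mm, seed) {
  set.seed(seed)
  k <- exp(-(geometry$dist^2) / (2 * length_mm^2))
  k <- k / rowSums(k)
  m <- as.vector(k %*% stats::rnorm(nrow(k)))
  names(m) <- geometry$regions
  m
}
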