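#' Pairwise Pearson correlation and p-value matrices for one subject
#'
#' Computes the node-by-node Pearson correlation matrix of a node-by-time
#' matrix, together with two-sided p-values from the exact t transform of
#' r with `n - 2` degrees of freedom.
#'
#' @param x numeric matrix, nodes in rows, time points in columns; row
#'   names are node ids.
#' @return list with `r` (correlations, unit diagonal) and `p` (two-sided
#'   p-values, diagonal 0).
#' @export
correlation_graph <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 3)
  v <- apply(x, 1, stats::sd)
  if (any(v == 0))
    stop("zero-variance node(s): ",
         paste(rownames(x)[v == 0], collapse = ", "))
  r <- stats::cor(t(x))
  n <- ncol(x)
  rr <- pmin(pmax(r, -1), 1)
  tstat <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  diag(r) <- 1
  list(r = r, p = p)
}

#' Benjamini-Hochberg rejection at level q
#'
#' Step-up procedure: reject all hypotheses with p at most the largest
#' p(k) satisfying p(k) <= k*q/m. Implemented through [stats::p.adjust()];
#' the test suite checks exact agreement with the brute-force definition.
#'
#' @param p numeric vector of p-values.
#' @param q FDR level in (0, 1).
#' @return logical vector of rejections.
#' @export
bh_reject <- function(p, q) {
  stopifnot(q > 0, q < 1)
  stats::p.adjust(p, method = "BH") <= q
}

#' FDR-threshold a correlation matrix into a positive-weight graph
#'
#' Benjamini-Hochberg correction is applied over the upper-triangle
#' p-values of the subject's matrix; edges that survive at level `q` AND
#' have positive correlation are retained with their r value, all other
#' entries are set to zero. Negative correlations are removed even when
#' significant.
#'
#' @param r,p correlation and p-value matrices from [correlation_graph()].
#' @param q FDR level in (0, 1).
#' @return a weighted graph: list with `weights` (symmetric nonnegative
#'   matrix, zero diagonal), `nodes`, and `q`.
#' @export
fdr_threshold <- function(r, p, q = 0.001) {
  stopifnot(identical(dim(r), dim(p)))
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ut <- upper.tri(p)
  keep_ut <- bh_reject(p[ut], q) & (r[ut] > 0)
  w <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  w[ut][keep_ut] <- r[ut][keep_ut]
  w <- w + t(w)
  structure(list(weights = w, nodes = rownames(r), q = q),
            class = "weighted_graph")
}

#' Fisher z-transform the weights of a thresholded graph
#'
#' Applies `atanh` to every retained correlation weight. The transform is
#' strictly monotone on (0, 1), so the ordering of edge strengths is
#' preserved. Off-diagonal weights of 1 or more (perfectly collinear
#' nodes) are rejected; they must be handled upstream.
#'
#' @param graph a weighted graph from [fdr_threshold()].
#' @return the graph with weights in Fisher-z units.
#' @export
fisher_z <- function(graph) {
  w <- graph$weights
  off <- w[upper.tri(w) | lower.tri(w)]
  if (any(off >= 1))
    stop("off-diagonal weight >= 1; perfectly collinear nodes upstream")
  graph$weights <- atanh(w)
  graph
}

#' Per-subject functional graph pipeline
#'
#' Correlation, FDR thresholding at level `q` with negative-edge removal,
#' and Fisher z-transformation, in one call.
#'
#' @inheritParams correlation_graph
#' @inheritParams fdr_threshold
#' @return a weighted graph in Fisher-z units.
#' @export
functional_graph <- function(x, q = 0.001) {
  cg <- correlation_graph(x)
  fisher_z(fdr_threshold(cg$r, cg$p, q))
}
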