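#' Write / read a numeric matrix as TSV with row and column ids
#'
#' Values round-trip at full double precision (15 significant digits via
#' the standard character conversion); ids round-trip exactly.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @param id_col name of the first (row-id) column.
#' @export
write_tsv_matrix <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @return `read_tsv_matrix`: the numeric matrix with dimnames restored.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Convert a weight matrix to an edge list and back
#'
#' `edge_list` lists each upper-triangle nonzero weight once as
#' (node_i, node_j, weight); `edge_list_to_matrix` is its inverse on the
#' given node set.
#'
#' @param w symmetric weight matrix with dimnames.
#' @return data.frame with `node_i`, `node_j`, `weight`.
#' @export
edge_list <- function(w) {
  stopifnot(!is.null(rownames(w)))
  ut <- which(upper.tri(w) & w != 0)
  n <- nrow(w)
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  data.frame(node_i = rownames(w)[i], node_j = rownames(w)[j],
             weight = w[ut], stringsAsFactors = FALSE)
}

#' @rdname edge_list
#' @param edges data.frame from [edge_list()].
#' @param nodes character vector of all node ids.
#' @export
edge_list_to_matrix <- function(edges, nodes) {
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  i <- match(edges$node_i, nodes)
  j <- match(edges$node_j, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge references unknown node id")
  w[cbind(i, j)] <- edges$weight
  w[cbind(j, i)] <- edges$weight
  w
}

#' Write / read gene-set collections in GMT format
#'
#' One term per line: term id, description, then member genes, tab
#' separated. Lines with fewer than three fields are rejected with their
#' line number.
#'
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @return `read_gmt`: named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    nm[i] <- f[1]
    out[[i]] <- f[-(1:2)]
  }
  names(out) <- nm
  out
}

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' A small deterministic string hash keeps the stochastic streams of the
#' pipeline stages independent while pinning everything to one master
#' seed. The result is a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name (character).
#' @return integer sub-seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483629 + 1)
}
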