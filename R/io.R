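#' Read and write the package's file formats
#'
#' Matrices travel as headered CSV (samples in rows, variables in columns);
#' edge sets as three-column TSV (\code{node_i}, \code{node_j},
#' \code{weight}) listing the upper-triangle edges; run manifests as JSON.
#'
#' @param path file path.
#' @param sep field separator (\code{","} or \code{"\t"} are both
#'   accepted on read).
#' @return \code{read_matrix_file}: a numeric matrix.
#' @name npn_io
NULL

#' @rdname npn_io
#' @export
read_matrix_file <- function(path, sep = c(",", "\t")) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else sep[1]
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  as.matrix(df)
}

#' @rdname npn_io
#' @param x matrix to write.
#' @export
write_matrix_file <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname npn_io
#' @param edges binary edge matrix.
#' @param weights optional weight matrix (e.g. \eqn{\hat\Omega}); defaults
#'   to the edge indicators.
#' @export
write_edges_file <- function(edges, path, weights = NULL) {
  edges <- as.matrix(edges)
  idx <- which(upper.tri(edges) & edges != 0, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[idx]
  nm <- colnames(edges)
  node <- function(i) if (is.null(nm)) as.character(i) else nm[i]
  df <- data.frame(node_i = node(idx[, 1]), node_j = node(idx[, 2]),
                   weight = w)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname npn_io
#' @param p number of nodes (edge files do not record isolated nodes).
#' @param nodes optional character vector of node names.
#' @export
read_edges_file <- function(path, p = NULL, nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(nodes)) {
    ids <- suppressWarnings(as.integer(unique(c(df$node_i, df$node_j))))
    if (any(is.na(ids))) {
      nodes <- sort(unique(c(as.character(df$node_i), as.character(df$node_j))))
    } else {
      nodes <- as.character(seq_len(max(c(ids, p))))
    }
  }
  if (is.null(p)) p <- length(nodes)
  E <- matrix(0L, p, p, dimnames = list(nodes[1:p], nodes[1:p]))
  for (r in seq_len(nrow(df))) {
    i <- match(as.character(df$node_i[r]), nodes)
    j <- match(as.character(df$node_j[r]), nodes)
    E[i, j] <- E[j, i] <- 1L
  }
  E
}

write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
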