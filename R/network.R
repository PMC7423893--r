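#' Construct a crosstalk network from an edge table
#'
#' Builds the undirected, binary functional-association network that all
#' crosstalk counting operates on.  Duplicate edges (in either orientation)
#' are collapsed to a single undirected link and self-links are dropped, so
#' the resulting adjacency matrix is symmetric with a zero diagonal.
#'
#' @param edges two-column character matrix or data.frame of gene pairs
#'   (one row per link; orientation irrelevant).
#' @param genes optional character vector of the gene universe.  Defaults to
#'   the genes appearing in `edges`; supply it to keep isolated genes.
#' @return An object of class `crosstalk_network`: a list with elements
#'   `genes` (character), `adj` (sparse symmetric 0/1 `dgCMatrix` with zero
#'   diagonal, dimnames = genes) and `degree` (named integer).
#' @export
network_from_edges <- function(edges, genes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  mode(edges) <- "character"
  if (is.null(genes)) {
    genes <- unique(c(edges[, 1L], edges[, 2L]))
  } else {
    genes <- unique(as.character(genes))
    miss <- setdiff(c(edges[, 1L], edges[, 2L]), genes)
    if (length(miss) > 0L)
      stop("edge endpoints not in supplied gene universe: ",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  ng <- length(genes)
  i <- match(edges[, 1L], genes)
  j <- match(edges[, 2L], genes)
  keep <- i != j                        # zero diagonal
  i <- i[keep]; j <- j[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * as.double(ng) + hi
  dup <- duplicated(key)
  lo <- lo[dup == FALSE]; hi <- hi[dup == FALSE]
  adj <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(ng, ng), dimnames = list(genes, genes)
  )
  net <- list(
    genes = genes,
    adj = adj,
    degree = stats::setNames(as.integer(Matrix::rowSums(adj)), genes)
  )
  class(net) <- "crosstalk_network"
  net
}

#' Load a functional-association network from an edge list file
#'
#' Reads a tab- or whitespace-separated edge list (columns: gene1, gene2 and
#' optionally a numeric link confidence; `#` comment lines ignored),
#' optionally thresholds on confidence, and returns the symmetric binary
#' network.  The gene universe is taken from the edges that survive the
#' confidence cutoff, so genes supported only by sub-threshold links are
#' excluded — mirroring how a confidence-thresholded FunCoup network is
#' conventionally used.
#'
#' @param path edge list file.
#' @param cutoff numeric link-confidence cutoff; edges with confidence
#'   `< cutoff` are dropped.  `NULL` (default) keeps all edges.
#' @param strict if `TRUE` (default) an empty file (or a file left empty by
#'   filtering) is an error; if `FALSE` it yields an empty network.
#' @return A [network_from_edges()] `crosstalk_network`.
#' @export
load_network <- function(path, cutoff = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("cannot read network file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, fill = FALSE,
                      colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    if (strict) stop("network file is empty: ", path)
    return(network_from_edges(matrix(character(), 0, 2)))
  }
  if (ncol(tab) < 2L) stop("network file must have >= 2 columns")
  if (!is.null(cutoff)) {
    if (ncol(tab) >= 3L) {
      conf <- suppressWarnings(as.numeric(tab[[3L]]))
      if (anyNA(conf))
        stop("non-numeric confidence values but a cutoff was given")
      tab <- tab[conf >= cutoff, , drop = FALSE]
    }
    # no third column: nothing to threshold, keep all edges
  }
  if (nrow(tab) == 0L) {
    if (strict) stop("no edges pass the confidence cutoff")
    return(network_from_edges(matrix(character(), 0, 2)))
  }
  network_from_edges(as.matrix(tab[, 1:2]))
}

#' Write a network as a two-column edge list
#'
#' Each undirected link is written once (lexicographically smaller gene
#' first).  Isolated genes are not representable in an edge list and are
#' omitted; reloading reproduces the adjacency relation exactly.
#'
#' @param network a `crosstalk_network`.
#' @param path output TSV path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "crosstalk_network"))
  tri <- Matrix::which(Matrix::triu(network$adj, k = 1) != 0, arr.ind = TRUE)
  df <- data.frame(gene1 = network$genes[tri[, 1L]],
                   gene2 = network$genes[tri[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.crosstalk_network <- function(x, ...) {
  n_edges <- sum(x$degree) / 2
  cat(sprintf("crosstalk network: %d genes, %d links\n",
              length(x$genes), as.integer(n_edges)))
  invisible(x)
}

# index of genes in the network universe; errors on absent genes
gene_index <- function(genes, network, what = "gene set") {
  idx <- match(genes, network$genes)
  if (anyNA(idx))
    stop(what, " contains genes absent from the network: ",
         paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
  idx
}
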