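#' Observed crosstalk between two gene sets
#'
#' Crosstalk is the ordered-pair link count
#' k = sum over (i in Q, j in P) of a_ij.  A link whose two endpoints both
#' lie in the overlap Q∩P therefore contributes twice, deliberately
#' boosting overlap cases; a link with exactly one endpoint in the overlap
#' contributes once; the zero diagonal means a gene never links to itself.
#'
#' @param q,p character vectors of gene ids, both subsets of the network
#'   universe.
#' @param network a `crosstalk_network`.
#' @return integer crosstalk degree k.
#' @export
count_crosstalk <- function(q, p, network) {
  iq <- gene_index(unique(q), network, "query")
  ip <- gene_index(unique(p), network, "pathway")
  as.integer(sum(network$adj[iq, ip, drop = FALSE]))
}

#' Number of possible links between a query and a pathway
#'
#' All ordered pairs minus the overlap (a gene cannot link to itself):
#' n = |Q||P| - |Q∩P|.
#'
#' @param q_size,p_size,overlap non-negative integers; `overlap` must not
#'   exceed the smaller set.
#' @return integer n.
#' @export
possible_links <- function(q_size, p_size, overlap) {
  if (any(c(q_size, p_size, overlap) < 0)) stop("sizes must be non-negative")
  if (overlap > min(q_size, p_size))
    stop("overlap exceeds the smaller set size")
  as.integer(q_size * p_size - overlap)
}

#' Per-gene link counts to a pathway
#'
#' For every network gene i, the number of links from i into the pathway.
#' Crosstalk of any query is then the sum of this vector over the query's
#' genes, which is what makes repeated null sampling against one pathway
#' cheap.
#'
#' @param network a `crosstalk_network`.
#' @param pathway character vector of pathway genes (subset of the network).
#' @return numeric vector, one entry per network gene.
#' @keywords internal
pathway_link_counts <- function(network, pathway) {
  ip <- gene_index(unique(pathway), network, "pathway")
  ind <- numeric(length(network$genes))
  ind[ip] <- 1
  as.numeric(network$adj %*% ind)
}

#' Bundle the crosstalk observation for one (query, pathway) pair
#'
#' By default the pathway is intersected with the network universe first and
#' `p_size` is the post-intersection size: genes without any possible link
#' cannot contribute crosstalk and would deflate the null if retained.
#' `pathway_universe = "full"` keeps the full pathway size in n instead.
#'
#' @param query a [map_query()] result (or character vector already inside
#'   the network).
#' @param pathway character vector of pathway genes.
#' @param network a `crosstalk_network`.
#' @param pathway_universe `"network"` (default) or `"full"`.
#' @return list of class `crosstalk_observation` with fields `k`, `n`,
#'   `overlap`, `q_size`, `p_size`.
#' @export
observe <- function(query, pathway, network,
                    pathway_universe = c("network", "full")) {
  pathway_universe <- match.arg(pathway_universe)
  q <- if (inherits(query, "mapped_query")) query$mapped else
    unique(as.character(query))
  if (length(q) == 0L) stop("query has no network support")
  pathway <- unique(as.character(pathway))
  p_net <- intersect(pathway, network$genes)
  p_size <- if (pathway_universe == "network") length(p_net)
            else length(pathway)
  ov <- if (pathway_universe == "network") length(intersect(q, p_net))
        else length(intersect(q, pathway))
  obs <- list(
    k = count_crosstalk(q, p_net, network),
    n = possible_links(length(q), p_size, ov),
    overlap = ov,
    q_size = length(q),
    p_size = p_size
  )
  class(obs) <- "crosstalk_observation"
  obs
}
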