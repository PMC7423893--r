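#' Specification for a synthetic network with planted pathway modules
#'
#' Describes a background gene network plus a set of planted modules:
#' disjoint gene groups whose internal pairs are linked with probability
#' `p_in` (dense, community-like — the regime in which real pathways make
#' crosstalk nulls overdispersed) and whose pairs to the rest of the
#' network get additional links with probability `p_out`.
#'
#' The defaults — 2000 genes, scale-free background (3 attachments per
#' gene), 10 modules of 80 genes with `p_in = 0.25`, `p_out = 0.005` —
#' give a minute-scale fixture whose planted pathways show the
#' overdispersion and module sizes typical of curated pathway databases.
#'
#' @param n_genes total genes.
#' @param background `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`.
#' @param m_attach edges per new gene for the scale-free background.
#' @param p_bg edge probability for the Erdos–Renyi background.
#' @param modules data.frame with columns `size`, `p_in` (one row per
#'   planted module), or a single pair recycled via `n_modules`.
#' @param n_modules number of modules when `modules` gives one row.
#' @param p_out module-to-background link probability (added on top of the
#'   background).
#' @param seed master seed; the network and each query batch use fixed
#'   offsets from it so every artifact is independently reproducible.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 2000,
                       background = c("scale_free", "erdos_renyi"),
                       m_attach = 3, p_bg = 0.002,
                       modules = data.frame(size = 80, p_in = 0.25),
                       n_modules = 10, p_out = 0.005, seed = 1) {
  background <- match.arg(background)
  if (nrow(modules) == 1L && n_modules > 1L)
    modules <- modules[rep(1L, n_modules), , drop = FALSE]
  if (sum(modules$size) > n_genes)
    stop("module sizes sum to more than n_genes")
  if (any(c(modules$p_in, p_out, p_bg) < 0) ||
      any(c(modules$p_in, p_out, p_bg) > 1))
    stop("probabilities must lie in [0, 1]")
  spec <- list(n_genes = as.integer(n_genes), background = background,
               m_attach = m_attach, p_bg = p_bg,
               modules = data.frame(size = as.integer(modules$size),
                                    p_in = modules$p_in),
               p_out = p_out, seed = as.integer(seed))
  class(spec) <- "synth_spec"
  spec
}

# sample pair indices from npairs possible with probability p, cheaply
sample_pairs <- function(npairs, p) {
  if (npairs == 0 || p <= 0) return(integer(0))
  ne <- stats::rbinom(1L, npairs, p)
  if (ne == 0L) return(integer(0))
  sample.int(npairs, ne)
}

# decode linear index (1..choose(n,2)) of the upper triangle to (i, j),
# with a guard against floating-point off-by-one at row boundaries
utri_decode <- function(idx, n) {
  idx <- as.double(idx) - 1
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  row_start <- function(i) i * n - i * (i + 1) / 2
  i <- i - (idx < row_start(i))
  i <- i + (idx >= row_start(i + 1))
  j <- idx - row_start(i) + i + 1
  cbind(as.integer(i + 1), as.integer(j + 1))
}

#' Generate a synthetic network with planted pathway modules
#'
#' Background edges follow the chosen random-graph model; within each
#' planted module every pair is linked with `p_in`; every (module gene,
#' outside gene) pair gets an extra link with `p_out`.  Module gene groups
#' are disjoint, sampled uniformly from the universe.  Deterministic given
#' the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return list with `network` (a `crosstalk_network`), `pathways` (a
#'   `geneset_collection` of the planted modules, ids `M01`, `M02`, ...)
#'   and `manifest` (realized parameters and edge counts).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(ng))
  if (spec$background == "scale_free") {
    g <- igraph::sample_pa(ng, m = spec$m_attach, directed = FALSE)
    bg <- igraph::as_edgelist(g, names = FALSE)
  } else {
    idx <- sample_pairs(choose(ng, 2), spec$p_bg)
    bg <- utri_decode(idx, ng)
  }
  perm <- sample.int(ng)            # detach module membership from pa order
  bg <- cbind(perm[bg[, 1L]], perm[bg[, 2L]])

  nmod <- nrow(spec$modules)
  mod_genes <- sample.int(ng, sum(spec$modules$size))
  splits <- rep(seq_len(nmod), spec$modules$size)
  members <- split(mod_genes, splits)
  edges_i <- bg[, 1L]; edges_j <- bg[, 2L]
  n_in <- integer(nmod); n_out <- integer(nmod)
  for (mi in seq_len(nmod)) {
    mem <- members[[mi]]
    sz <- length(mem)
    idx <- sample_pairs(choose(sz, 2), spec$modules$p_in[mi])
    if (length(idx) > 0L) {
      ij <- utri_decode(idx, sz)
      edges_i <- c(edges_i, mem[ij[, 1L]])
      edges_j <- c(edges_j, mem[ij[, 2L]])
    }
    n_in[mi] <- length(idx)
    outside <- setdiff(seq_len(ng), mem)
    oidx <- sample_pairs(sz * length(outside), spec$p_out)
    if (length(oidx) > 0L) {
      r <- ((oidx - 1L) %% sz) + 1L
      c_ <- ((oidx - 1L) %/% sz) + 1L
      edges_i <- c(edges_i, mem[r])
      edges_j <- c(edges_j, outside[c_])
    }
    n_out[mi] <- length(oidx)
  }
  net <- network_from_edges(cbind(genes[edges_i], genes[edges_j]),
                            genes = genes)
  sets <- stats::setNames(lapply(members, function(m) genes[sort(m)]),
                          sprintf("M%02d", seq_len(nmod)))
  pathways <- geneset_collection(sets)
  manifest <- list(
    n_genes = ng, background = spec$background,
    m_attach = spec$m_attach, p_bg = spec$p_bg,
    modules = data.frame(id = names(sets), size = spec$modules$size,
                         p_in = spec$modules$p_in,
                         realized_internal_edges = n_in,
                         realized_outgoing_edges = n_out),
    p_out = spec$p_out, seed = spec$seed,
    n_edges_total = sum(net$degree) / 2,
    expected_internal_edges = choose(spec$modules$size, 2) * spec$modules$p_in
  )
  list(network = net, pathways = pathways, manifest = manifest)
}

#' Generate a query gene set against a synthetic (or real) network
#'
#' `mode = "random"` draws a uniform sample of distinct network genes —
#' the ingredient of false-positive benchmarks.  `mode = "enriched"` takes
#' `ceiling(fraction * size)` genes from the named pathway and fills the
#' remainder from outside it, providing planted positives.
#'
#' @param mode `"random"` or `"enriched"`.
#' @param size query size.
#' @param network a `crosstalk_network`.
#' @param pathways `geneset_collection` (required for enriched mode).
#' @param pathway_id id of the enriched pathway.
#' @param fraction fraction of the query taken from the pathway.
#' @param seed optional seed.
#' @return character vector of gene ids.
#' @export
generate_query <- function(mode = c("random", "enriched"), size, network,
                           pathways = NULL, pathway_id = NULL,
                           fraction = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ng <- length(network$genes)
  if (size > ng) stop("query size exceeds the network universe")
  if (mode == "random" || fraction == 0)
    return(network$genes[sample.int(ng, size)])
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  pw <- pathways$sets[[pathway_id]]
  if (is.null(pw)) stop("unknown pathway id: ", pathway_id)
  pw <- intersect(pw, network$genes)
  n_in <- ceiling(fraction * size)
  if (n_in > length(pw))
    stop("pathway smaller than the required enriched portion")
  inside <- sample(pw, n_in)
  outside_pool <- setdiff(network$genes, pw)
  if (size - n_in > length(outside_pool))
    stop("not enough genes outside the pathway")
  c(inside, sample(outside_pool, size - n_in))
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the four standard artifacts: network edge list (TSV), planted
#' pathways (GMT), query sets (GMT) and a JSON manifest recording every
#' parameter and seed needed to regenerate them.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if missing).
#' @param n_queries number of random queries to write.
#' @param query_size their size.
#' @return invisible named character vector of the four file paths.
#' @export
write_fixture <- function(spec, dir, n_queries = 10, query_size = 110) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_network(spec)
  paths <- c(network = file.path(dir, "network.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             queries = file.path(dir, "queries.gmt"),
             manifest = file.path(dir, "manifest.json"))
  write_network(fx$network, paths[["network"]])
  write_gmt(fx$pathways, paths[["pathways"]])
  qsets <- lapply(seq_len(n_queries), function(i)
    generate_query("random", query_size, fx$network,
                   seed = (spec$seed + 1000L + i) %% 2147483647L))
  names(qsets) <- sprintf("Q%03d", seq_len(n_queries))
  write_gmt(geneset_collection(qsets), paths[["queries"]])
  manifest <- fx$manifest
  manifest$modules <- as.list(manifest$modules)
  manifest$n_queries <- n_queries
  manifest$query_size <- query_size
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
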