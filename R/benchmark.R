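#' False-positive benchmark: random query sets against every pathway
#'
#' Draws `n_sets` random gene sets from the network universe and tests
#' each against every pathway with the full sampling + beta-binomial
#' pipeline.  A calibrated test should flag about 5% of random sets at
#' p < 0.05 for every pathway, with uniformly distributed p-values.
#'
#' @param network a `crosstalk_network`.
#' @param pathways a `geneset_collection`.
#' @param n_sets number of random query sets (the canonical protocol uses
#'   10,000).
#' @param set_size query size (110, the mean size of MSigDB gene sets).
#' @param m null draws per pathway.
#' @param seed master seed.
#' @return data.frame with one row per pathway: `pathway_id`, `n_tests`,
#'   `fpr` (fraction of mid p < 0.05), `fpr_fdr` (fraction significant at
#'   per-query BH FDR < 0.05), `uniformity_stat` (KS distance to U(0,1),
#'   descriptive — mid p-values are discrete), `flag` (`"no_links"` for
#'   untestable pathways, excluded from summaries).  Attribute `"summary"`
#'   holds the grand-mean FPR over testable pathways; attribute
#'   `"p_matrix"` the n_sets x n_pathways mid-p matrix.
#' @export
fp_benchmark <- function(network, pathways, n_sets = 10000, set_size = 110,
                         m = 2000, seed = 1) {
  npw <- length(pathways$sets)
  ids <- names(pathways$sets)
  empty <- data.frame(pathway_id = character(), n_tests = integer(),
                      fpr = numeric(), fpr_fdr = numeric(),
                      uniformity_stat = numeric(), flag = character(),
                      stringsAsFactors = FALSE)
  if (n_sets == 0L || npw == 0L) return(empty)
  ng <- length(network$genes)
  set.seed(as.integer((seed + 424243) %% 2147483647))
  queries <- lapply(seq_len(n_sets), function(i) sample.int(ng, set_size))

  pmat <- matrix(NA_real_, n_sets, npw, dimnames = list(NULL, ids))
  flag <- character(npw)
  for (pi in seq_len(npw)) {
    pw <- intersect(pathways$sets[[pi]], network$genes)
    v <- if (length(pw)) pathway_link_counts(network, pw) else
      numeric(ng)
    if (sum(v) == 0) { flag[pi] <- "no_links"; next }
    sub_seed <- as.integer((seed + 7919 * pi + set_size) %% 2147483647)
    ns <- sample_null(network, pw, set_size, m = m, seed = sub_seed)
    fit <- fit_beta_binomial(ns)
    ip <- match(pw, network$genes)
    in_p <- logical(ng); in_p[ip] <- TRUE
    pmat[, pi] <- vapply(queries, function(qi) {
      k <- sum(v[qi])
      ov <- sum(in_p[qi])
      fit_mid_p(fit, k, possible_links(set_size, length(pw), ov))
    }, numeric(1))
  }
  testable <- flag == ""
  qmat <- pmat
  if (any(testable))
    qmat[, testable] <- t(apply(pmat[, testable, drop = FALSE], 1L,
                                bh_adjust))
  rows <- data.frame(
    pathway_id = ids,
    n_tests = ifelse(testable, n_sets, 0L),
    fpr = colMeans(pmat < 0.05),
    fpr_fdr = colMeans(qmat < 0.05),
    uniformity_stat = apply(pmat, 2L, ks_distance_uniform),
    flag = flag, stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  attr(rows, "summary") <- list(
    mean_fpr = mean(rows$fpr[testable]),
    mean_fpr_fdr = mean(rows$fpr_fdr[testable]),
    n_sets = n_sets, set_size = set_size, m = m, seed = seed)
  attr(rows, "p_matrix") <- pmat
  rows
}

# one-sample KS distance to U(0,1); descriptive only
ks_distance_uniform <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  s <- sort(p)
  n <- length(s)
  max(pmax(abs(seq_len(n) / n - s), abs(s - (seq_len(n) - 1) / n)))
}

#' Bisect a pathway into two link-balanced halves
#'
#' Splits the pathway's network genes into two disjoint parts of sizes
#' differing by at most one, then greedily swaps gene pairs between the
#' parts (best improving single swap each round, up to `max_swaps`
#' accepted swaps) until no single swap reduces the difference in
#' within-part link counts.  Deterministic given the seed.
#'
#' @param pathway character vector of pathway genes.
#' @param network a `crosstalk_network`.
#' @param seed optional seed for the initial random split.
#' @param max_swaps cap on accepted refinement swaps.
#' @return list with `part1`, `part2` (character vectors) and
#'   `part_link_counts` (within-part link counts after refinement).
#' @export
bisect_pathway <- function(pathway, network, seed = NULL, max_swaps = 200) {
  if (!is.null(seed)) set.seed(seed)
  genes <- intersect(unique(as.character(pathway)), network$genes)
  sz <- length(genes)
  if (sz < 4L) stop("pathway too small to bisect (needs >= 4 network genes)")
  A <- as.matrix(network$adj[match(genes, network$genes),
                             match(genes, network$genes)])
  half <- sz %/% 2L
  in1 <- logical(sz)
  in1[sample.int(sz, half)] <- TRUE
  links_within <- function(mask) sum(A[mask, mask]) / 2
  for (it in seq_len(max_swaps)) {
    c1 <- as.vector(A %*% in1)          # per-gene links into part1
    c2 <- as.vector(A %*% (!in1))
    L1 <- sum(c1[in1]) / 2
    L2 <- sum(c2[!in1]) / 2
    i1 <- which(in1); i2 <- which(!in1)
    # swap g1 (part1 -> part2) with g2 (part2 -> part1)
    newL1 <- L1 - outer(c1[i1], rep(1, length(i2))) +
      outer(rep(1, length(i1)), c1[i2]) - t(A[i2, i1, drop = FALSE])
    newL2 <- L2 - outer(rep(1, length(i1)), c2[i2]) +
      outer(c2[i1], rep(1, length(i2))) - t(A[i2, i1, drop = FALSE])
    objs <- abs(newL1 - newL2)
    best <- which(objs == min(objs), arr.ind = TRUE)[1L, ]
    if (min(objs) >= abs(L1 - L2)) break
    in1[i1[best[1L]]] <- FALSE
    in1[i2[best[2L]]] <- TRUE
  }
  list(part1 = genes[in1], part2 = genes[!in1],
       part_link_counts = c(links_within(in1), links_within(!in1)))
}

#' Emulate gene overlap between two bisected pathway parts
#'
#' Copies `overlap_count` randomly chosen genes of `part2` into `part1`
#' (membership added, nothing removed), so the parts share exactly that
#' many genes.  Mirrors the average overlap real experimental gene sets
#' have with pathways, which overlap-based methods require.
#'
#' @param part1,part2 character vectors (disjoint).
#' @param overlap_count number of shared genes to create.
#' @param seed optional seed.
#' @return list with the new `part1` and unchanged `part2`.
#' @export
emulate_overlap <- function(part1, part2, overlap_count, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (overlap_count > min(length(part1), length(part2)))
    stop("overlap_count exceeds the smaller part")
  if (overlap_count > 0L)
    part1 <- c(part1, sample(part2, overlap_count))
  list(part1 = part1, part2 = part2)
}

#' True-positive benchmark: reconnecting bisected pathways
#'
#' Each pathway is bisected into link-balanced halves, optional overlap is
#' emulated, and part1 (as the query) is tested against part2 (as the
#' pathway) with the full pipeline.  A true positive is the crosstalk
#' between two parts of the same pathway; the summary TPR is the fraction
#' significant at BH FDR < 0.05 across pathways.
#'
#' @param network a `crosstalk_network`.
#' @param pathways a `geneset_collection`.
#' @param overlap_table optional named integer vector (pathway id ->
#'   emulated overlap); missing entries mean 0.
#' @param m null draws per test.
#' @param seed master seed.
#' @return data.frame with one row per bisectable pathway: `pathway_id`,
#'   `part_size1`, `part_size2`, `part_links1`, `part_links2`,
#'   `overlap_emulated`, `p_value`, `q_value`.  Attribute `"summary"`
#'   holds the TPR at FDR < 0.05 and the count of skipped pathways.
#' @export
tp_benchmark <- function(network, pathways, overlap_table = NULL, m = 2000,
                         seed = 1) {
  rows <- list(); skipped <- character()
  for (pi in seq_along(pathways$sets)) {
    pid <- names(pathways$sets)[pi]
    pw <- intersect(pathways$sets[[pi]], network$genes)
    if (length(pw) < 4L) { skipped <- c(skipped, pid); next }
    sub_seed <- as.integer((seed + 31337 * pi) %% 2147483647)
    bis <- bisect_pathway(pw, network, seed = sub_seed)
    ov <- 0L
    if (!is.null(overlap_table) && pid %in% names(overlap_table))
      ov <- as.integer(overlap_table[[pid]])
    parts <- emulate_overlap(bis$part1, bis$part2, ov)
    obs <- observe(parts$part1, parts$part2, network)
    ns <- sample_null(network, parts$part2, length(unique(parts$part1)),
                      m = m,
                      seed = as.integer((seed + 7919 * pi + 1) %% 2147483647))
    fit <- fit_beta_binomial(ns)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pid,
      part_size1 = length(unique(parts$part1)),
      part_size2 = length(parts$part2),
      part_links1 = bis$part_link_counts[1L],
      part_links2 = bis$part_link_counts[2L],
      overlap_emulated = ov,
      p_value = fit_mid_p(fit, obs$k, obs$n),
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    message(length(skipped), " pathway(s) too small to bisect, skipped")
  if (length(rows) == 0L) {
    out <- data.frame(pathway_id = character(), part_size1 = integer(),
                      part_size2 = integer(), part_links1 = numeric(),
                      part_links2 = numeric(), overlap_emulated = integer(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- list(tpr_fdr05 = NA_real_, skipped = skipped)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  attr(out, "summary") <- list(tpr_fdr05 = mean(out$q_value < 0.05),
                               skipped = skipped, m = m, seed = seed)
  out
}

#' ROC points from true- and false-positive p-values
#'
#' Sweeps the significance threshold over the union of observed p-values;
#' at each threshold TPR is the fraction of true-positive tests at or
#' below it and FPR likewise for false-positive tests.
#'
#' @param tp_pvalues,fp_pvalues non-empty numeric vectors.
#' @return data.frame of `(fpr, tpr)` points, non-decreasing in both
#'   coordinates, anchored at (0,0) and (1,1); attribute `"auc"` is the
#'   trapezoidal area under the curve.
#' @export
roc_points <- function(tp_pvalues, fp_pvalues) {
  if (length(tp_pvalues) == 0L || length(fp_pvalues) == 0L)
    stop("both p-value vectors must be non-empty")
  th <- sort(unique(c(tp_pvalues, fp_pvalues)))
  tpr <- vapply(th, function(t) mean(tp_pvalues <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(fp_pvalues <= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[!duplicated(pts), ]
  rownames(pts) <- NULL
  attr(pts, "auc") <- sum(diff(pts$fpr) *
                            (utils::head(pts$tpr, -1) +
                               utils::tail(pts$tpr, -1)) / 2)
  pts
}

#' Stability of the sampled null: coefficient of variation across
#' regenerated nulls
#'
#' The null is sampled, so the p-value is a point estimate.  For each
#' pathway and each null size `m`, the null is regenerated `reps` times;
#' the CV (SD/mean) of the null means measures how stable the fitted null
#' is, and the SD of log mid p-values for the supplied query measures how
#' much reported significance moves between runs.  A CV below 2% is the
#' conventional stability requirement, reached at about 2000 draws.
#'
#' @param network a `crosstalk_network`.
#' @param pathways a `geneset_collection`.
#' @param query character vector (a fixed query scored under each
#'   replicate null).
#' @param sample_sizes integer vector of null sizes m to profile.
#' @param reps replicate nulls per (pathway, m).
#' @param seed master seed.
#' @return data.frame with columns `pathway_id`, `n_samples`, `cv`,
#'   `sd_log_p`; attribute `"summary"`: fraction of pathways with
#'   CV < 2% per sample size.
#' @export
stability_analysis <- function(network, pathways, query,
                               sample_sizes = c(100, 500, 2000),
                               reps = 100, seed = 1) {
  if (reps < 2L) stop("need at least two replicates")
  mq <- suppressMessages(map_query(query, network))
  qsize <- length(mq$mapped)
  rows <- list()
  for (pi in seq_along(pathways$sets)) {
    pid <- names(pathways$sets)[pi]
    pw <- intersect(pathways$sets[[pi]], network$genes)
    obs <- observe(mq, pw, network)
    for (m in sample_sizes) {
      means <- numeric(reps); logp <- numeric(reps)
      for (r in seq_len(reps)) {
        sub_seed <- as.integer((seed + 7919 * pi + 131 * m + r) %%
                                 2147483647)
        ns <- sample_null(network, pw, qsize, m = m, seed = sub_seed)
        means[r] <- mean(ns$counts)
        logp[r] <- log(fit_mid_p(fit_beta_binomial(ns), obs$k, obs$n))
      }
      grand <- mean(means)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid, n_samples = as.integer(m),
        cv = if (grand == 0) NA_real_ else stats::sd(means) / grand,
        sd_log_p = stats::sd(logp), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  frac <- vapply(sample_sizes, function(m)
    mean(out$cv[out$n_samples == m] < 0.02, na.rm = TRUE), numeric(1))
  attr(out, "summary") <- data.frame(n_samples = as.integer(sample_sizes),
                                     frac_cv_below_2pct = frac)
  out
}

#' Fraction of a pathway's links that are internal
#'
#' Edges with both endpoints inside the pathway divided by edges touching
#' the pathway at all.  High values mean the pathway behaves as an
#' isolated community — precisely the pathways for which random-gene-set
#' null models misestimate crosstalk.
#'
#' @param pathway character vector of genes.
#' @param network a `crosstalk_network`.
#' @return numeric in \[0, 1\], or `NA` if the pathway has no incident
#'   links.
#' @export
intralink_fraction <- function(pathway, network) {
  pw <- intersect(unique(as.character(pathway)), network$genes)
  if (length(pw) == 0L) return(NA_real_)
  idx <- match(pw, network$genes)
  internal <- sum(network$adj[idx, idx]) / 2
  incident <- sum(network$degree[idx]) - internal
  if (incident == 0) return(NA_real_)
  internal / incident
}

#' Number of maximal cliques in a pathway's induced subgraph
#'
#' A clique is any complete subgraph; it is maximal if no further node can
#' be added.  Many maximal cliques indicate a topologically non-random
#' pathway.  Isolated vertices count as maximal 1-cliques by default.
#'
#' @param pathway character vector of genes.
#' @param network a `crosstalk_network`.
#' @param min_size smallest clique size counted (default 1).
#' @return integer count.
#' @export
count_maximal_cliques <- function(pathway, network, min_size = 1) {
  pw <- intersect(unique(as.character(pathway)), network$genes)
  if (length(pw) == 0L) return(0L)
  idx <- match(pw, network$genes)
  g <- igraph::graph_from_adjacency_matrix(
    network$adj[idx, idx, drop = FALSE], mode = "undirected")
  igraph::count_max_cliques(g, min = min_size)
}

#' Pathway-topology diagnostics for a collection
#'
#' @param network a `crosstalk_network`.
#' @param pathways a `geneset_collection`.
#' @return data.frame with `pathway_id`, `intralink_fraction`,
#'   `total_links` (links touching the pathway) and `n_maximal_cliques`.
#' @export
topology_diagnostics <- function(network, pathways) {
  rows <- lapply(seq_along(pathways$sets), function(pi) {
    pw <- intersect(pathways$sets[[pi]], network$genes)
    idx <- match(pw, network$genes)
    internal <- if (length(idx)) sum(network$adj[idx, idx]) / 2 else 0
    incident <- if (length(idx)) sum(network$degree[idx]) - internal else 0
    data.frame(pathway_id = names(pathways$sets)[pi],
               intralink_fraction =
                 if (incident == 0) NA_real_ else internal / incident,
               total_links = as.integer(incident),
               n_maximal_cliques =
                 count_maximal_cliques(pw, network),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise gene overlap between pathways
#'
#' Jaccard-style shared fraction |A∩B| / |A∪B| for every unordered pair.
#' Highly overlapping pathways produce strongly dependent enrichment
#' calls.
#'
#' @param pathways a `geneset_collection` with >= 2 sets.
#' @return data.frame with `id1`, `id2`, `shared_fraction_of_union`.
#' @export
pairwise_overlap <- function(pathways) {
  ids <- names(pathways$sets)
  if (length(ids) < 2L) stop("need at least two sets")
  cmb <- utils::combn(length(ids), 2L)
  data.frame(
    id1 = ids[cmb[1L, ]], id2 = ids[cmb[2L, ]],
    shared_fraction_of_union = apply(cmb, 2L, function(ij) {
      a <- pathways$sets[[ij[1L]]]; b <- pathways$sets[[ij[2L]]]
      length(intersect(a, b)) / length(union(a, b))
    }), stringsAsFactors = FALSE)
}
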