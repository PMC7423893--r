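#' One-tailed mid p-value under a beta-binomial null
#'
#' Tests enrichment only: H0 "no more links between Q and P than expected
#' by chance" against H1 "more links".  Because the null is discrete,
#' ordinary p-values are conservative; the mid p-value — half the
#' probability of the observed statistic plus the probability of more
#' extreme values, P(X > k) + 0.5 P(X = k) — corrects this.  The tail is
#' summed exactly over the discrete support via log-sum-exp; no normal
#' approximation is used.
#'
#' @param k_obs observed crosstalk, in 0..n.
#' @param n possible links.
#' @param alpha,beta fitted beta-binomial parameters.
#' @return mid p-value, floored at 1e-300.
#' @export
mid_p_value <- function(k_obs, n, alpha, beta) {
  if (k_obs < 0 || k_obs > n) stop("k_obs outside 0..n")
  lp <- betabinom_logpmf(k_obs:n, n, alpha, beta)
  midp_from_logpmf_tail(lp)
}

# tail logpmf vector starting at the observed value
midp_from_logpmf_tail <- function(lp) {
  p_eq <- exp(lp[1L])
  p_gt <- if (length(lp) > 1L) {
    mx <- max(lp[-1L])
    if (is.finite(mx)) exp(mx) * sum(exp(lp[-1L] - mx)) else 0
  } else 0
  min(max(p_gt + 0.5 * p_eq, 1e-300), 1 - 1e-16)
}

# mid p under the binomial fallback
binom_mid_p <- function(k_obs, n, p_hat) {
  val <- stats::pbinom(k_obs, n, p_hat, lower.tail = FALSE) +
    0.5 * stats::dbinom(k_obs, n, p_hat)
  min(max(val, 1e-300), 1 - 1e-16)
}

# mid p from the raw null counts (degenerate fits); clamped into (0,1)
empirical_mid_p <- function(k_obs, counts) {
  m <- length(counts)
  val <- (sum(counts > k_obs) + 0.5 * sum(counts == k_obs)) / m
  min(max(val, 0.5 / (m + 1)), 1 - 0.5 / (m + 1))
}

# mid p for one observation given a fit, honouring fallbacks
fit_mid_p <- function(fit, k_obs, n_obs) {
  switch(fit$fallback,
    none = mid_p_value(k_obs, n_obs, fit$alpha, fit$beta),
    binomial = binom_mid_p(k_obs, n_obs, fit$p_hat),
    empirical = empirical_mid_p(k_obs, fit$counts)
  )
}

#' Benjamini–Hochberg q-values
#'
#' Standard step-up FDR adjustment with enforced monotonicity; ties keep
#' input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full crosstalk-enrichment pipeline
#'
#' For every (query, pathway) pair: map the query onto the network, count
#' observed crosstalk and possible links, build (or reuse) the
#' pathway-specific null at the mapped query size, fit the beta-binomial,
#' and compute the one-tailed mid p-value.  Null samples are cached per
#' (pathway, query size), so several same-size queries share one fit; each
#' null draw is seeded by a fixed function of the master seed, the pathway
#' index and the query size, making results deterministic regardless of
#' evaluation order.
#'
#' @param queries a `geneset_collection` (or single character vector).
#' @param pathways a `geneset_collection`.
#' @param network a `crosstalk_network`.
#' @param m null draws per (pathway, size) (default 2000).
#' @param seed master seed; `NULL` uses the current RNG state (then only
#'   run-to-run determinism under an outer `set.seed` holds).
#' @param correction_scope `"per_query"` (default; BH across the pathways
#'   each query is compared to, the single-user scenario) or `"global"`
#'   (one BH across all tests, for batch studies).
#' @param pathway_universe passed to [observe()].
#' @param cache optional environment reused across calls to share null
#'   fits.
#' @return data.frame with one row per (query, pathway): `query_id`,
#'   `pathway_id`, `k`, `n`, `overlap`, `alpha`, `beta`, `mid_p`,
#'   `q_value`, `flags` (comma-joined subset of `degenerate`,
#'   `binomial_fallback`, `low_support`); rows sorted by
#'   (query_id, mid_p).  Queries without network support are skipped with
#'   a warning.
#' @export
run_anubix <- function(queries, pathways, network, m = 2000, seed = NULL,
                       correction_scope = c("per_query", "global"),
                       pathway_universe = c("network", "full"),
                       cache = NULL) {
  correction_scope <- match.arg(correction_scope)
  pathway_universe <- match.arg(pathway_universe)
  if (is.character(queries))
    queries <- geneset_collection(list(query = queries))
  stopifnot(inherits(queries, "geneset_collection"),
            inherits(pathways, "geneset_collection"),
            inherits(network, "crosstalk_network"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  empty <- data.frame(query_id = character(), pathway_id = character(),
                      k = integer(), n = integer(), overlap = integer(),
                      alpha = numeric(), beta = numeric(),
                      mid_p = numeric(), q_value = numeric(),
                      flags = character(), stringsAsFactors = FALSE)
  if (length(pathways$sets) == 0L || length(queries$sets) == 0L)
    return(empty)

  rows <- list()
  for (qid in names(queries$sets)) {
    mq <- tryCatch(suppressMessages(map_query(queries$sets[[qid]], network)),
                   error = function(e) NULL)
    if (is.null(mq)) {
      warning("query '", qid, "' has no network support; skipped")
      next
    }
    qsize <- length(mq$mapped)
    low_support <- qsize < 5L || length(mq$dropped) > length(mq$mapped)
    for (pi in seq_along(pathways$sets)) {
      pid <- names(pathways$sets)[pi]
      pw <- pathways$sets[[pi]]
      obs <- observe(mq, pw, network, pathway_universe)
      fit <- cached_null_fit(cache, network, pw, pid, pi, qsize, m, seed)
      midp <- fit_mid_p(fit, obs$k, obs$n)
      flags <- c(if (fit$degenerate) "degenerate",
                 if (fit$fallback == "binomial") "binomial_fallback",
                 if (low_support) "low_support")
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, pathway_id = pid, k = obs$k, n = obs$n,
        overlap = obs$overlap,
        alpha = if (is.null(fit$alpha)) NA_real_ else fit$alpha,
        beta = if (is.null(fit$beta)) NA_real_ else fit$beta,
        mid_p = midp, q_value = NA_real_,
        flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  if (correction_scope == "per_query") {
    for (qid in unique(res$query_id)) {
      sel <- res$query_id == qid
      res$q_value[sel] <- bh_adjust(res$mid_p[sel])
    }
  } else {
    res$q_value <- bh_adjust(res$mid_p)
  }
  res <- res[order(res$query_id, res$mid_p), ]
  rownames(res) <- NULL
  res
}

# fetch-or-build the null fit for (pathway, size); derived per-pathway seed
cached_null_fit <- function(cache, network, pathway, pid, pindex, qsize, m,
                            seed) {
  key <- paste0(pid, "||", qsize)
  if (!is.null(cache[[key]])) return(cache[[key]])
  sub_seed <- if (is.null(seed)) NULL
    else as.integer((as.double(seed) + 7919 * pindex + qsize) %% 2147483647)
  ns <- sample_null(network, pathway, qsize, m = m, seed = sub_seed)
  fit <- fit_beta_binomial(ns)
  cache[[key]] <- fit
  fit
}

#' Confidence interval for a sampled p-value
#'
#' The reported p-value is a point estimate: it depends on the random null
#' sample behind it.  Given replicate mid p-values for the same test under
#' independently regenerated nulls, this returns a central-limit-theorem
#' normal interval for the mean, computed on the log scale and
#' back-transformed when all replicates are positive (p-value spread is
#' proportional to p-value magnitude), linear scale otherwise.
#'
#' @param replicate_mid_ps numeric vector of replicate p-values (>= 2).
#' @param level confidence level (default 0.95).
#' @param scale `"log"` (default) or `"linear"`.
#' @return named numeric `c(low, high)`, clipped to \[0, 1\].
#' @export
pvalue_confidence_interval <- function(replicate_mid_ps, level = 0.95,
                                       scale = c("log", "linear")) {
  scale <- match.arg(scale)
  r <- length(replicate_mid_ps)
  if (r < 2L) stop("need at least two replicates")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "log" && all(replicate_mid_ps > 0)) {
    lp <- log(replicate_mid_ps)
    ctr <- mean(lp); hw <- z * stats::sd(lp) / sqrt(r)
    ci <- exp(c(ctr - hw, ctr + hw))
  } else {
    ctr <- mean(replicate_mid_ps)
    hw <- z * stats::sd(replicate_mid_ps) / sqrt(r)
    ci <- c(ctr - hw, ctr + hw)
  }
  ci <- pmin(pmax(ci, 0), 1)
  stats::setNames(ci, c("low", "high"))
}

#' Write an enrichment result table as TSV
#'
#' @param results data.frame from [run_anubix()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
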