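#' Sample a pathway-specific crosstalk null distribution
#'
#' Draws `m` uniform random gene sets of `set_size` distinct genes from the
#' network universe and records each draw's crosstalk to the intact
#' pathway.  Pathway genes are not excluded from the draws: overlap can
#' occur and its links are double-counted, exactly as in the observed
#' statistic.  The possible-link count `n` stored with the sample is the
#' overlap-free `set_size * p_size` — the overlap of a modest random draw
#' with one pathway in a large universe is negligible, and a fixed n is
#' what the beta-binomial fit requires.
#'
#' @param network a `crosstalk_network`.
#' @param pathway character vector of pathway genes (intersected with the
#'   network internally).
#' @param set_size query size the null is built for.
#' @param m number of random draws (default 2000, at which the mean of the
#'   null is stable to a coefficient of variation below 2%).
#' @param seed optional integer; when given the draw is seeded and
#'   reproducible in isolation.
#' @return Object of class `null_sample`: list with `pathway_id`,
#'   `set_size`, `n`, `counts` (length m), `m`, `seed`.
#' @export
sample_null <- function(network, pathway, set_size, m = 2000, seed = NULL) {
  if (m < 2L) stop("need at least two null draws")
  ng <- length(network$genes)
  if (set_size > ng) stop("set_size exceeds the network universe")
  if (!is.null(seed)) set.seed(seed)
  p_net <- intersect(unique(as.character(pathway)), network$genes)
  v <- pathway_link_counts(network, p_net)
  counts <- vapply(seq_len(m),
                   function(i) sum(v[sample.int(ng, set_size)]),
                   numeric(1))
  out <- list(pathway_id = attr(pathway, "id") %||% NA_character_,
              set_size = as.integer(set_size),
              n = possible_links(set_size, length(p_net), 0L),
              counts = as.integer(counts), m = as.integer(m),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  class(out) <- "null_sample"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta-binomial log probability mass
#'
#' log of C(n,k) * B(k+alpha, n-k+beta) / B(alpha, beta), evaluated
#' entirely in log-gamma space.  With alpha = beta = 1 this is the discrete
#' uniform on 0..n; as alpha+beta grows at fixed mean it approaches the
#' binomial.
#'
#' @param k integer vector in 0..n.
#' @param n number of possible links.
#' @param alpha,beta positive shape parameters of the mixing beta.
#' @return numeric vector of log probabilities.
#' @export
betabinom_logpmf <- function(k, n, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (any(k < 0 | k > n)) stop("k outside 0..n")
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

#' Beta-binomial negative log-likelihood
#'
#' Minus the summed log-likelihood of the counts, with the binomial
#' coefficient dropped: it does not depend on the parameters being
#' optimized, so removing it leaves the location of the optimum untouched
#' while avoiding needless large-argument log-gamma evaluations.
#'
#' @param counts integer vector of crosstalk counts.
#' @param n possible links (common to all counts).
#' @param alpha,beta positive shape parameters.
#' @return scalar; non-finite values signal parameter overflow to the
#'   optimizer.
#' @export
betabinom_nll <- function(counts, n, alpha, beta) {
  if (alpha <= 0 || beta <= 0) return(Inf)
  -sum(lgamma(alpha + counts) + lgamma(beta + n - counts) -
         lgamma(alpha + beta + n) - lgamma(alpha) - lgamma(beta) +
         lgamma(alpha + beta))
}

#' Random beta-binomial deviates
#'
#' @param m number of draws.
#' @param n trials per draw.
#' @param alpha,beta positive shape parameters.
#' @return integer vector of length m.
#' @export
rbetabinom <- function(m, n, alpha, beta) {
  stats::rbinom(m, n, stats::rbeta(m, alpha, beta))
}

#' Fit a beta-binomial to a crosstalk null sample by maximum likelihood
#'
#' Minimizes [betabinom_nll()] with Nelder–Mead over (log alpha, log beta),
#' so positivity is enforced by the parameterization.  The start point
#' comes from the method of moments: with sample mean mbar and variance v,
#' p0 = mbar/n, rho0 = clamp((v/(n p0 (1-p0)) - 1)/(n-1), 1e-6, 1-1e-6),
#' alpha0 = p0(1-rho0)/rho0, beta0 = (1-p0)(1-rho0)/rho0.
#'
#' Failures are encoded in flags rather than raised: a zero-variance sample
#' is `degenerate` (fallback `"empirical"`), and a fitted alpha+beta above
#' 1e7 is declared the binomial limit (fallback `"binomial"` with
#' p_hat = mean/n; such a fit is numerically indistinguishable from a
#' binomial, which non-overdispersed pathways fit equally well).
#'
#' @param sample a [sample_null()] result, or a list with `counts` and `n`.
#' @param maxit Nelder–Mead iteration cap.
#' @param reltol convergence tolerance on the negative log-likelihood.
#' @param od_cap overdispersion cap on alpha+beta beyond which the
#'   binomial limit is declared.
#' @return Object of class `betabinom_fit`: list with `alpha`, `beta`, `n`,
#'   `loglik`, `converged`, `degenerate`, `fallback`
#'   (`"none"`, `"binomial"` or `"empirical"`), `p_hat`, and (for the
#'   empirical fallback) the raw `counts`.
#' @export
fit_beta_binomial <- function(sample, maxit = 2000, reltol = 1e-8,
                              od_cap = 1e7) {
  counts <- sample$counts
  n <- sample$n
  m <- length(counts)
  if (m < 2L) stop("need at least two counts to fit")
  mbar <- mean(counts)
  v <- stats::var(counts)
  base <- list(n = as.integer(n), p_hat = mbar / max(n, 1L),
               counts = as.integer(counts))
  if (v == 0 || n == 0L) {
    out <- c(list(alpha = NA_real_, beta = NA_real_, loglik = NA_real_,
                  converged = FALSE, degenerate = TRUE,
                  fallback = "empirical"), base)
    class(out) <- "betabinom_fit"
    return(out)
  }
  p0 <- min(max(mbar / n, 1e-9), 1 - 1e-9)
  rho0 <- (v / (n * p0 * (1 - p0)) - 1) / (n - 1)
  rho0 <- min(max(rho0, 1e-6), 1 - 1e-6)
  a0 <- p0 * (1 - rho0) / rho0
  b0 <- (1 - p0) * (1 - rho0) / rho0
  obj <- function(lp) {
    val <- betabinom_nll(counts, n, exp(lp[1L]), exp(lp[2L]))
    if (!is.finite(val)) 1e12 else val
  }
  opt <- stats::optim(c(log(a0), log(b0)), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  alpha <- exp(opt$par[1L]); beta <- exp(opt$par[2L])
  converged <- opt$convergence == 0L && is.finite(opt$value)
  fallback <- "none"
  if (!converged && !is.finite(opt$value)) {
    fallback <- "empirical"
  } else if (alpha + beta > od_cap) {
    fallback <- "binomial"
  } else {
    # data with no real overdispersion fit a binomial equally well: the
    # beta-binomial MLE then sits at (or drifts toward) the alpha+beta ->
    # Inf boundary and the extra parameter buys nothing.  Compare against
    # the binomial at its MLE p_hat by likelihood ratio (same dropped
    # binomial-coefficient constant on both sides).
    ph <- min(max(mbar / n, 1e-12), 1 - 1e-12)
    nll_binom <- -sum(counts * log(ph) + (n - counts) * log(1 - ph))
    if (2 * (nll_binom - opt$value) < stats::qchisq(0.95, 1))
      fallback <- "binomial"
  }
  out <- c(list(alpha = alpha, beta = beta, loglik = -opt$value,
                converged = converged, degenerate = FALSE,
                fallback = fallback), base)
  class(out) <- "betabinom_fit"
  out
}

#' Fit the baseline binomial to a null sample
#'
#' The diagnostic baseline: a single success probability p_hat = mean/n.
#' Overdispersed nulls (most pathways) are fit poorly by it, which is the
#' motivation for the beta-binomial.
#'
#' @param sample a [sample_null()] result, or list with `counts`, `n`.
#' @return list of class `binom_fit` with `p_hat` and `n`.
#' @export
fit_binomial <- function(sample) {
  if (sample$n == 0L) stop("no possible links: n = 0")
  out <- list(p_hat = mean(sample$counts) / sample$n,
              n = as.integer(sample$n))
  class(out) <- "binom_fit"
  out
}

#' Dispersion of a null sample
#'
#' Variance-to-mean ratio of the crosstalk counts (unbiased sample
#' variance).  Values above 1 indicate overdispersion relative to a
#' Poisson/binomial benchmark; nearly all real pathway nulls are
#' overdispersed, which is what the beta-binomial accommodates.
#'
#' @param sample a [sample_null()] result.
#' @return numeric ratio, or `NA` when the mean is zero.
#' @export
dispersion <- function(sample) {
  mbar <- mean(sample$counts)
  if (mbar == 0) return(NA_real_)
  stats::var(sample$counts) / mbar
}
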