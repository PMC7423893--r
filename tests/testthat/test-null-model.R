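test_that("beta-binomial log-pmf matches closed forms and normalizes", {
  # alpha = beta = 1 is the discrete uniform on 0..n
  expect_equal(betabinom_logpmf(3, 10, 1, 1), log(1 / 11))
  expect_equal(betabinom_logpmf(0:2, 2, 1, 1), rep(log(1 / 3), 3))

  # independent log-gamma evaluation of C(5,2) B(4,6) / B(2,3)
  oracle <- lgamma(6) - lgamma(3) - lgamma(4) +
    (lgamma(4) + lgamma(6) - lgamma(10)) -
    (lgamma(2) + lgamma(3) - lgamma(5))
  expect_equal(betabinom_logpmf(2, 5, 2, 3), oracle)
  expect_equal(exp(oracle), 5 / 21)

  expect_equal(sum(exp(betabinom_logpmf(0:50, 50, 0.7, 4.2))), 1,
               tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:300, 1)
    a <- stats::rlnorm(1); b <- stats::rlnorm(1, 1)
    expect_equal(sum(exp(betabinom_logpmf(0:n, n, a, b))), 1,
                 tolerance = 1e-10)
  }
  expect_error(betabinom_logpmf(5, 4, 1, 1), "outside")
  expect_error(betabinom_logpmf(1, 4, -1, 1), "positive")
})

test_that("negative log-likelihood matches hand evaluation and is additive", {
  # one count of 0 out of n = 1 under the uniform (alpha = beta = 1):
  # with the binomial coefficient dropped the value is log 2
  expect_equal(betabinom_nll(0L, 1L, 1, 1), log(2))

  counts <- c(3L, 3L, 3L)
  expect_equal(betabinom_nll(counts, 10L, 2, 5),
               3 * betabinom_nll(3L, 10L, 2, 5))

  # the NLL at the generating parameters beats a badly distorted pair
  set.seed(44)
  sim <- rbetabinom(5000, 100, 2, 8)
  expect_lt(betabinom_nll(sim, 100L, 2, 8),
            betabinom_nll(sim, 100L, 20, 0.8))
})

test_that("null sampling is seeded, bounded and matches its expectation", {
  fx <- default_fixture()
  pw <- fx$pathways$sets$M03
  ns1 <- sample_null(fx$network, pw, 110, m = 200, seed = 9)
  ns2 <- sample_null(fx$network, pw, 110, m = 200, seed = 9)
  expect_identical(ns1$counts, ns2$counts)
  expect_length(ns1$counts, 200)
  expect_true(all(ns1$counts >= 0 & ns1$counts <= ns1$n))
  expect_equal(ns1$n, 110 * length(pw))

  # sample mean of counts within 3 standard errors of the exact
  # finite-population expectation set_size * mean(per-gene links to P)
  v <- anubix:::pathway_link_counts(fx$network, pw)
  big <- sample_null(fx$network, pw, 110, m = 2000, seed = 10)
  se <- stats::sd(big$counts) / sqrt(big$m)
  expect_lt(abs(mean(big$counts) - 110 * mean(v)), 3 * se)

  expect_error(sample_null(fx$network, pw, 1e6), "exceeds")
  expect_error(sample_null(fx$network, pw, 10, m = 1), "two null draws")
})

test_that("pathway with no links yields an all-zero, degenerate null", {
  net <- network_from_edges(rbind(c("a", "b")), genes = c("a", "b", "x", "y"))
  ns <- sample_null(net, c("x", "y"), 2, m = 50, seed = 1)
  expect_true(all(ns$counts == 0))
  fit <- fit_beta_binomial(ns)
  expect_true(fit$degenerate)
  expect_equal(fit$fallback, "empirical")
})

test_that("maximum likelihood recovers beta-binomial parameters", {
  set.seed(55)
  counts <- rbetabinom(5000, 500, 2, 50)
  fit <- fit_beta_binomial(list(counts = counts, n = 500L))
  expect_true(fit$converged)
  expect_equal(fit$fallback, "none")
  expect_lt(abs(fit$alpha - 2) / 2, 0.2)
  expect_lt(abs(fit$beta - 50) / 50, 0.2)

  # coarse grid-search oracle: the optimizer's NLL is at least as good as
  # the best point on a log-alpha x log-beta grid around the truth
  grid <- expand.grid(la = log(2) + seq(-1, 1, length.out = 21),
                      lb = log(50) + seq(-1, 1, length.out = 21))
  grid_nll <- mapply(function(la, lb)
    betabinom_nll(counts, 500L, exp(la), exp(lb)), grid$la, grid$lb)
  expect_lte(betabinom_nll(counts, 500L, fit$alpha, fit$beta),
             min(grid_nll) + 1e-6)
})

test_that("binomial-generated counts collapse to the binomial limit", {
  set.seed(2)
  counts <- stats::rbinom(5000, 200, 0.05)
  fit <- fit_beta_binomial(list(counts = counts, n = 200L))
  expect_equal(fit$fallback, "binomial")
  # fitted mean within 2% of the generating mean n*p
  expect_lt(abs(200 * fit$alpha / (fit$alpha + fit$beta) - 10) / 10, 0.02)
  expect_lt(abs(200 * fit$p_hat - 10) / 10, 0.02)
})

test_that("refitting from the optimum moves the NLL by less than 1e-6", {
  set.seed(66)
  counts <- rbetabinom(3000, 300, 3, 20)
  fit <- fit_beta_binomial(list(counts = counts, n = 300L))
  refit <- stats::optim(log(c(fit$alpha, fit$beta)), function(lp)
    betabinom_nll(counts, 300L, exp(lp[1]), exp(lp[2])),
    method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-8))
  expect_lt(abs(refit$value - (-fit$loglik)), 1e-6)
})

test_that("fitted beta-binomial variance dominates the matched binomial", {
  fx <- default_fixture()
  ns <- sample_null(fx$network, fx$pathways$sets$M01, 110, m = 1000,
                    seed = 21)
  fit <- fit_beta_binomial(ns)
  p <- fit$alpha / (fit$alpha + fit$beta)
  infl <- (fit$alpha + fit$beta + fit$n) / (fit$alpha + fit$beta + 1)
  expect_gte(fit$n * p * (1 - p) * infl, fit$n * p * (1 - p))
  expect_gt(infl, 1)
})

test_that("binomial baseline fit and dispersion follow their definitions", {
  expect_equal(fit_binomial(list(counts = c(1L, 3L), n = 4L))$p_hat, 0.5)
  expect_equal(fit_binomial(list(counts = c(0L, 0L), n = 7L))$p_hat, 0)
  expect_error(fit_binomial(list(counts = 0L, n = 0L)), "n = 0")

  set.seed(77)
  sim <- stats::rbinom(4000, 50, 0.1)
  bfit <- fit_binomial(list(counts = sim, n = 50L))
  se <- sqrt(0.1 * 0.9 / (50 * 4000))
  expect_lt(abs(bfit$p_hat - 0.1), 3 * se)

  expect_equal(dispersion(list(counts = rep(4L, 10))), 0)
  expect_true(is.na(dispersion(list(counts = rep(0L, 10)))))
  set.seed(78)
  pois <- stats::rpois(20000, 30)
  expect_equal(dispersion(list(counts = pois)), 1, tolerance = 0.05)
})
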