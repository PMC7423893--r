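# shared helpers: tiny literal networks and one cached synthetic fixture

toy_network <- function(...) {
  # toy_network("a-b", "b-c") builds a network from dash-separated edges
  pairs <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
  network_from_edges(pairs)
}

random_toy_graph <- function(n, p = 0.3) {
  # dense random graph with a plain matrix alongside, for oracle checks
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1L, p)
  A <- A + t(A)
  genes <- paste0("g", seq_len(n))
  dimnames(A) <- list(genes, genes)
  edges <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  net <- network_from_edges(cbind(genes[edges[, 1]], genes[edges[, 2]]),
                            genes = genes)
  list(net = net, A = A, genes = genes)
}

# brute-force maximal-clique count by subset enumeration (oracle)
brute_max_cliques <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(0L)
  subsets <- lapply(seq_len(2^n - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2L) return(TRUE)
    all(A[s, s][upper.tri(A[s, s])] == 1L)
  }, logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(i) {
    s <- cl[[i]]
    !any(vapply(cl, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  sum(maximal)
}

# textbook step-up BH (oracle, independent of p.adjust)
textbook_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# the default synthetic fixture, built once per test run
default_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generate_network(synth_spec(seed = 42))
    fx
  }
})
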