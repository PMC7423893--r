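test_that("pathway bisection balances genes and links", {
  # 4-cycle: every balanced split (corner pairs or opposite corners) has
  # equal within-part link counts, verified by exhaustive enumeration, so
  # any of them is a valid locally minimal answer
  net <- toy_network("a-b", "b-c", "c-d", "d-a")
  bis <- bisect_pathway(c("a", "b", "c", "d"), net, seed = 3)
  expect_equal(unname(lengths(bis[c("part1", "part2")])), c(2L, 2L))
  expect_equal(diff(bis$part_link_counts), 0)
  all_splits <- utils::combn(c("a", "b", "c", "d"), 2, simplify = FALSE)
  gaps <- vapply(all_splits, function(p1) {
    p2 <- setdiff(c("a", "b", "c", "d"), p1)
    abs(count_crosstalk(p1, p1, net) - count_crosstalk(p2, p2, net)) / 2
  }, numeric(1))
  expect_equal(abs(diff(bis$part_link_counts)), min(gaps))

  # isolated genes: any balanced split is valid
  net2 <- network_from_edges(rbind(c("x", "y")),
                             genes = c("p", "q", "r", "s", "x", "y"))
  bis2 <- bisect_pathway(c("p", "q", "r", "s"), net2, seed = 4)
  expect_equal(unname(lengths(bis2[c("part1", "part2")])), c(2L, 2L))
  expect_equal(bis2$part_link_counts, c(0, 0))

  # 6-clique: every 3/3 split leaves 3 links on each side
  genes <- letters[1:6]
  edges <- t(utils::combn(genes, 2))
  net3 <- network_from_edges(edges)
  bis3 <- bisect_pathway(genes, net3, seed = 5)
  expect_equal(bis3$part_link_counts, c(3, 3))

  expect_error(bisect_pathway(c("a", "b", "c"), net), "too small")
})

test_that("bisection is seed-deterministic and refinement helps", {
  fx <- default_fixture()
  pw <- fx$pathways$sets$M05
  b1 <- bisect_pathway(pw, fx$network, seed = 17)
  b2 <- bisect_pathway(pw, fx$network, seed = 17)
  expect_identical(b1, b2)
  expect_lte(abs(length(b1$part1) - length(b1$part2)), 1)
  # refined split is no worse than the average random balanced split
  set.seed(18)
  rand_gap <- replicate(20, {
    in1 <- sample(length(pw), length(pw) %/% 2)
    idx <- match(pw, fx$network$genes)
    A <- as.matrix(fx$network$adj[idx, idx])
    abs(sum(A[in1, in1]) - sum(A[-in1, -in1])) / 2
  })
  expect_lte(abs(diff(b1$part_link_counts)), mean(rand_gap))
})

test_that("overlap emulation adds shared genes without removing any", {
  p1 <- c("a", "b"); p2 <- c("c", "d")
  same <- emulate_overlap(p1, p2, 0)
  expect_identical(same$part1, p1)

  one <- emulate_overlap(p1, p2, 1, seed = 6)
  expect_length(intersect(one$part1, one$part2), 1)
  expect_true(all(p1 %in% one$part1))
  expect_identical(one$part2, p2)

  full <- emulate_overlap(p1, p2, 2, seed = 7)
  expect_true(all(p2 %in% full$part1))
  expect_error(emulate_overlap(p1, p2, 3), "exceeds")
})

test_that("ROC points sweep thresholds correctly", {
  pts <- roc_points(rep(0.001, 5), rep(0.9, 5))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
  expect_equal(attr(pts, "auc"), 1)

  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))

  set.seed(19)
  same <- stats::runif(2000)
  pts2 <- roc_points(same[1:1000], same[1001:2000])
  expect_equal(attr(pts2, "auc"), 0.5, tolerance = 0.05)

  pts3 <- roc_points(rep(0.5, 3), rep(0.5, 3))
  expect_equal(nrow(pts3), 2)  # degenerate: anchors (0,0) and (1,1) only
  expect_error(roc_points(numeric(), 0.5), "non-empty")
})

test_that("intralink fraction counts internal versus incident links", {
  clique <- toy_network("a-b", "b-c", "a-c")
  expect_equal(intralink_fraction(c("a", "b", "c"), clique), 1)

  star <- toy_network("hub-a", "hub-b", "hub-c")
  expect_equal(intralink_fraction(c("a", "b", "c"), star), 0)

  toy <- toy_network("a-b", "b-x")
  expect_equal(intralink_fraction(c("a", "b"), toy), 0.5)

  lonely <- network_from_edges(rbind(c("a", "b")), genes = c("a", "b", "z"))
  expect_true(is.na(intralink_fraction("z", lonely)))
})

test_that("maximal clique counts match exhaustive enumeration", {
  tri <- toy_network("a-b", "b-c", "a-c")
  expect_equal(count_maximal_cliques(c("a", "b", "c"), tri), 1L)
  path <- toy_network("a-b", "b-c")
  expect_equal(count_maximal_cliques(c("a", "b", "c"), path), 2L)

  set.seed(20)
  for (i in 1:8) {
    g <- random_toy_graph(sample(6:12, 1), p = 0.4)
    expect_equal(count_maximal_cliques(g$genes, g$net),
                 brute_max_cliques(g$A))
  }
  # min_size = 2 drops isolated vertices
  iso <- network_from_edges(rbind(c("a", "b")), genes = c("a", "b", "z"))
  expect_equal(count_maximal_cliques(c("a", "b", "z"), iso), 2L)
  expect_equal(count_maximal_cliques(c("a", "b", "z"), iso, min_size = 2), 1L)
})

test_that("pairwise overlap is the shared fraction of the union", {
  gs <- geneset_collection(list(s1 = c("a", "b", "c"), s2 = c("b", "c", "d"),
                                s3 = c("a", "b", "c"), s4 = c("x")))
  ov <- pairwise_overlap(gs)
  expect_equal(nrow(ov), 6)
  get <- function(i, j) ov$shared_fraction_of_union[ov$id1 == i & ov$id2 == j]
  expect_equal(get("s1", "s2"), 0.5)
  expect_equal(get("s1", "s3"), 1)
  expect_equal(get("s1", "s4"), 0)
  expect_error(pairwise_overlap(geneset_collection(list(only = "a"))),
               "at least two")
})

test_that("FP benchmark emits per-pathway calibration rows", {
  fx <- default_fixture()
  pws <- geneset_collection(c(fx$pathways$sets[1:2],
                              list(dead = c("zzz1", "zzz2"))))
  expect_equal(nrow(fp_benchmark(fx$network, pws, n_sets = 0)), 0)

  fb <- fp_benchmark(fx$network, pws, n_sets = 150, set_size = 110,
                     m = 500, seed = 23)
  expect_equal(fb$pathway_id, c("M01", "M02", "dead"))
  expect_equal(fb$flag, c("", "", "no_links"))
  expect_true(all(fb$fpr[1:2] >= 0 & fb$fpr[1:2] <= 1))
  expect_true(all(fb$uniformity_stat[1:2] <= 1))
  summ <- attr(fb, "summary")
  expect_equal(summ$mean_fpr, mean(fb$fpr[1:2]))
  # FDR-corrected significance can only be rarer than raw significance
  expect_true(all(fb$fpr_fdr[1:2] <= fb$fpr[1:2] + 1e-12))
})

test_that("TP benchmark reconnects planted halves; random sets do not", {
  fx <- default_fixture()
  pws <- geneset_collection(fx$pathways$sets[1:5])
  tp <- tp_benchmark(fx$network, pws, m = 500, seed = 29)
  expect_equal(nrow(tp), 5)
  expect_true(all(tp$part_size1 + tp$part_size2 == 80))
  expect_true(all(tp$q_value < 0.05))  # dense modules reconnect easily

  # overlap emulation feeds through to the observation
  tp_ov <- tp_benchmark(fx$network, pws,
                        overlap_table = c(M01 = 5L), m = 500, seed = 29)
  expect_equal(tp_ov$overlap_emulated[tp_ov$pathway_id == "M01"], 5L)
  expect_equal(tp_ov$part_size1[tp_ov$pathway_id == "M01"], 45L)

  # pathways that are random vertex sets behave like the null
  set.seed(30)
  rand_pws <- geneset_collection(list(
    R1 = sample(fx$network$genes, 60), R2 = sample(fx$network$genes, 60),
    R3 = sample(fx$network$genes, 60), R4 = sample(fx$network$genes, 60)))
  tp_null <- tp_benchmark(fx$network, rand_pws, m = 500, seed = 31)
  expect_gt(min(tp_null$p_value), 0.01)
})

test_that("stability analysis reports CV per null size", {
  fx <- default_fixture()
  pws <- geneset_collection(fx$pathways$sets[1:2])
  q <- generate_query("random", 60, fx$network, seed = 35)
  st <- stability_analysis(fx$network, pws, q,
                           sample_sizes = c(50, 400), reps = 20, seed = 36)
  expect_equal(nrow(st), 4)
  expect_true(all(st$cv >= 0, na.rm = TRUE))
  # standard error of the null mean shrinks with more draws
  mean_cv <- tapply(st$cv, st$n_samples, mean)
  expect_lt(mean_cv[["400"]], mean_cv[["50"]])
  summ <- attr(st, "summary")
  expect_equal(summ$n_samples, c(50L, 400L))
  expect_error(stability_analysis(fx$network, pws, q, reps = 1), "two")
})

test_that("topology diagnostics summarize every pathway", {
  fx <- default_fixture()
  td <- topology_diagnostics(fx$network, fx$pathways)
  expect_equal(td$pathway_id, names(fx$pathways$sets))
  expect_true(all(td$intralink_fraction > 0 & td$intralink_fraction <= 1))
  expect_true(all(td$n_maximal_cliques >= 1))
})
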