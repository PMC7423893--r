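---
title: "Pathway-specific null models for network crosstalk enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-specific null models for network crosstalk enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Given a query gene set $Q$ (say, a list of differentially expressed genes)
and a curated pathway $P$, crosstalk enrichment asks whether $Q$ has more
links to $P$ in a functional association network than chance would
produce.  The network is an undirected graph over genes with a symmetric
binary adjacency $a_{ij} \in \{0,1\}$, zero on the diagonal, typically
obtained by thresholding a confidence-scored resource such as FunCoup or
STRING.

The crosstalk statistic is the ordered-pair link count

$$k \;=\; \sum_{i \in Q} \sum_{j \in P} a_{ij},$$

so a link between two genes that both lie in $Q \cap P$ contributes twice.
This is deliberate: overlap between a query and a pathway is evidence of
association, and double counting boosts it.  The number of possible links
is $n = |Q||P| - |Q \cap P|$ (a gene cannot link to itself).

## Why the null must be pathway-specific

Methods that model the expected crosstalk by treating *both* sets as
random (binomial, hypergeometric or chi-square nulls) implicitly assume
the pathway looks like a random gene set.  Real pathways do not: they are
densely intra-connected communities with heavy-tailed degree profiles.
The consequence is empirical: sample many random query sets against a
fixed pathway and the distribution of $k$ has variance well above its
mean, i.e. it is overdispersed relative to any binomial with the same
mean.  A binomial null then underestimates the spread and floods the
analysis with false positives, and it does so unevenly — the most
community-like pathways (high intralink fraction, many maximal cliques)
are hit hardest, biasing results toward exactly the famous pathways users
most want to believe.

The approach here keeps the pathway intact and randomizes only the query:
for each pathway and query size, crosstalk counts of `m` random gene sets
drawn uniformly from the network universe form an empirical null
(`sample_null()`).  Each count is a sum of dependent Bernoulli variables
whose success probability varies from draw to draw — precisely the regime
the beta-binomial handles, by letting the link probability itself follow
a $\mathrm{Beta}(\alpha, \beta)$:

$$f(k \mid n, \alpha, \beta) \;=\; \binom{n}{k}
  \frac{B(k+\alpha,\; n-k+\beta)}{B(\alpha, \beta)}.$$

The parameters are estimated by maximum likelihood
(`fit_beta_binomial()`): the negative log-likelihood, written entirely in
log-gamma terms with the $\binom{n}{k}$ constant dropped (it does not
depend on the parameters), is minimized by Nelder–Mead over
$(\log\alpha, \log\beta)$, which enforces positivity without constraints.
The start point is the method-of-moments estimate.

Significance of an observed $k$ is a one-tailed **mid p-value**,

$$p_{\text{mid}} = P(X > k) + \tfrac{1}{2} P(X = k),$$

summed exactly over the discrete support (no normal approximation):
ordinary p-values on discrete supports are conservative, and the mid-p
correction restores calibration.  Only enrichment is tested; depletion is
out of scope.  Benjamini–Hochberg correction is applied across the
pathways each query is compared to (`correction_scope = "per_query"`,
the single-user scenario) or across all tests (`"global"`, for batch
studies).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` (null draws) | 2000 | draws per (pathway, query size); at 2000 the coefficient of variation of the null mean is below 2% for essentially all pathways — the conventional stability requirement |
| confidence `cutoff` | none | applied to column 3 of the edge list when given (0.75 is the usual FunCoup choice); the gene universe is the *post-filter* one |
| `pathway_universe` | `"network"` | pathways are intersected with the network before counting; genes with no links cannot contribute crosstalk and would deflate the null if retained. `"full"` keeps the raw pathway size in $n$ |
| `correction_scope` | `"per_query"` | BH across pathways per query |
| `size_threshold`, `target_mean_size` | 20, 80 | hierarchy collapsing: leaves below the threshold merge into their parents, with the threshold raised one gene at a time, until the mean set size reaches the target (80 genes, the KEGG-like scale) |

## Numerical choices

* **Fit tolerances.** Nelder–Mead with `reltol = 1e-8` on the NLL and at
  most 2000 iterations; refitting from the optimum moves the NLL by less
  than $10^{-6}$.
* **The binomial limit.** The beta-binomial degenerates to the binomial
  as $\alpha + \beta \to \infty$.  For null samples with no real
  overdispersion the MLE sits at that boundary and the optimizer stalls
  on a flat likelihood at some large but arbitrary $\alpha + \beta$.  Two
  triggers therefore declare the binomial limit: a hard cap
  ($\hat\alpha + \hat\beta > 10^7$), and a likelihood-ratio comparison
  against the binomial at $\hat p = \bar k / n$ (threshold
  $\chi^2_{0.95,1}$) — if the extra parameter buys no significant
  likelihood, such a null fits a binomial equally well and the mid
  p-value is computed from the binomial pmf instead.
* **Degenerate nulls.** Zero-variance samples (e.g. a pathway with no
  links) cannot be fit; the empirical distribution of the counts is used
  directly, with the mid p-value clamped into
  $[\tfrac{1}{2(m+1)},\, 1 - \tfrac{1}{2(m+1)}]$ so it stays inside
  $(0,1)$.
* **$n$ for the fit vs. $n$ for the test.** Random draws overlap the
  pathway by a varying, tiny amount (a 110-gene draw meets an 80-gene
  pathway in a 2000-gene universe about 4 genes on average, and far
  fewer in a 12k-gene one), so the fit uses the overlap-free
  $n = |Q| \cdot |P|$; the observed statistic still uses the exact
  $n = |Q||P| - |Q \cap P|$.
* **Floors.** Mid p-values are floored at $10^{-300}$ so downstream
  $\log p$ never overflows.
* **Determinism.** Every null draw is seeded by a fixed function of the
  master seed, the pathway index and the query size, so results do not
  depend on evaluation order, and identical seeds give bitwise-identical
  runs.  Null fits are cached per (pathway, query size) within a run.

## The synthetic-data generator

`synth_spec()` / `generate_network()` build networks with *planted
pathway modules*: a background graph (scale-free by preferential
attachment with 3 attachments per gene, or Erdős–Rényi) over `n_genes`
genes, plus disjoint modules whose internal pairs are linked with
`p_in` and whose pairs to the outside receive additional links with
`p_out`.  The default fixture — 2000 genes, 10 modules of 80 genes,
`p_in = 0.25`, `p_out = 0.005` — was chosen once as the smallest
configuration that reproduces the phenomena the method is built around:
module sizes on the KEGG scale (~80 genes), a heavy-tailed background
degree distribution, and null crosstalk distributions to planted modules
that are overdispersed for essentially every module.  Query sets come
from `generate_query()`: uniform random draws (the false-positive
protocol) or sets seeded with a fraction of a named module's genes
(planted positives).

What the generator does *not* emulate: the evidence-integration structure
of real functional association networks (correlated link confidences,
study bias toward well-annotated genes), overlapping pathway membership,
and annotation noise.  Tests passing on these fixtures therefore
demonstrate the statistical machinery — calibration under the null,
power against dense modules, overdispersion handling — not performance on
any particular real database.

## The benchmark protocols

* `fp_benchmark()` — random sets of size 110 (the mean size of MSigDB
  gene sets) against every pathway; per-pathway false-positive rate at
  $p < 0.05$, at per-query FDR < 0.05, and a descriptive KS distance to
  uniformity (descriptive because mid p-values are discrete and
  "stagger" when the statistic's support is small).
* `tp_benchmark()` — each pathway is bisected into halves with similar
  gene and within-part link counts (random balanced split, then a greedy
  best-single-swap hill-climb on the link-count difference, at most 200
  accepted swaps — a simple, seeded, testable stand-in for more elaborate
  graph-partitioning schemes), optional emulated overlap is added to the
  query half, and the halves are tested against each other; TPR is the
  fraction significant at FDR < 0.05.
* `stability_analysis()` — the null regenerated repeatedly at several
  sizes `m`; CV of the null means and SD of log mid p-values.
* `topology_diagnostics()` — intralink fraction and maximal-clique
  counts, the two topology measures that correlate with false-positive
  inflation in random-set null models.
* `roc_points()` — threshold sweep over TP and FP p-value sets with a
  trapezoidal AUC.

## A worked example

```{r example, eval = FALSE}
library(anubix)

fx <- generate_network(synth_spec(seed = 1))
query <- generate_query("enriched", size = 110, fx$network, fx$pathways,
                        pathway_id = "M03", fraction = 0.5, seed = 2)
res <- run_anubix(geneset_collection(list(myquery = query)),
                  fx$pathways, fx$network, m = 2000, seed = 3)
head(res, 3)
```

The enriched module tops the table with a mid p-value many orders of
magnitude below the rest; the nine undisturbed modules are spread over
$(0,1)$ as a calibrated null demands.

## Problem sizes used in the test suite

The shipped tests run entirely on synthetic fixtures at sizes chosen to
finish in minutes while keeping every statistical check meaningful: the
2000-gene default fixture for calibration (1000 random queries, 2000-draw
nulls), 100 planted modules across ten fixture replicates for the
overdispersion survey (1000-draw nulls), 60 replicate nulls per
(pathway, m) for the stability profile over $m \in \{100, 500, 2000\}$,
and a 5000-gene network with 50 planted modules for the
bisection/discrimination benchmark.

## Known limitations

* Enrichment only; no depletion or two-tailed testing.
* The null depends on Monte Carlo sampling: p-values are point estimates
  with sampling error (quantify with
  `pvalue_confidence_interval()`; 2000 draws keep the CV of the null
  mean under 2%).
* One null fit is shared across queries of the same size; queries whose
  mapped sizes differ all need their own fits, which dominates run time
  for large heterogeneous batches.
* Highly overlapping pathways give strongly dependent results
  (`pairwise_overlap()` quantifies this); BH correction does not remove
  that dependence.
* Gene identifiers are opaque case-sensitive strings; identifier
  translation is upstream of this package.
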