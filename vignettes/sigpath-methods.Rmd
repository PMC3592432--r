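---
title: "Topology-aware two-sample pathway analysis: models, tests and design choices"
author: "sigpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware two-sample pathway analysis: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpath)
```

## The problem

Most gene set tests reduce a curated pathway to a flat list of genes. But a
pathway is a wiring diagram: only some routes through it are expected to react
to a phenotype, and a test that ignores the wiring cannot say *which* route
reacted. `sigpath` addresses both questions for a two-phenotype expression
study. Step 1 asks whether a pathway as a whole behaves differently in the two
classes — in its mean expression and, separately, in the strength of its
gene–gene links. Step 2 walks the pathway's junction tree and extracts the
chains of cliques (the "signal sub-paths") that carry the association.

## Models

Let $G$ be the undirected graph obtained from the pathway (after the topology
pipeline below) on $P$ genes. Each class $k \in \{1, 2\}$ is modelled as a
graphical Gaussian model sharing $G$:

$$ Y^{(k)} \sim N_P(\mu_k, \Sigma_k), \qquad K_k = \Sigma_k^{-1} \in S^+(G), $$

where $S^+(G)$ is the cone of symmetric positive definite matrices whose
entries vanish off the edges of $G$: a missing edge means conditional
independence of the two genes given the rest. Two null hypotheses are tested:
equality of the concentration matrices, $K_1 = K_2$ (the links), and equality
of the means, $\mu_1 = \mu_2$.

## From pathway to junction tree

Curated pathway graphs are directed and may be cyclic; graphical-model
machinery needs a decomposable undirected graph. The pipeline is:

1. **Self-loop removal** — a gene regulating itself carries no information
   for a Gaussian Markov structure.
2. **Cycle breaking** — while a directed cycle exists, the cycle edge whose
   endpoint expression profiles have the smallest absolute Pearson
   correlation (all samples pooled) is deleted. Pooling both classes avoids
   making the topology class-dependent; using the absolute value treats
   activation and repression symmetrically. Cycle detection uses depth-first
   search with lexicographic vertex order, so runs are reproducible; an exact
   correlation tie is broken toward the lexicographically smallest edge.
3. **Moralization** — parents sharing a child are joined and directions
   dropped; this is the graph $G$ whose Markov structure the models use.
4. **Triangulation** — greedy minimum-fill elimination with lexicographic
   tie-breaks. Minimum fill keeps maximal cliques small, and clique size is
   what limits estimability: a clique of $c$ genes needs more than $c$
   samples for an unpenalized clique-wise covariance estimate.
5. **Cliques and junction tree** — maximal cliques of the triangulated graph
   become nodes of a maximum-weight spanning tree on separator size (Kruskal
   order, lexicographic tie-break), which for a chordal graph satisfies the
   running intersection property. The root is the clique whose members come
   first in the maximum cardinality search ordering. Disconnected pathways
   are analyzed one connected component at a time, as separate "pathway
   components".

The concentration matrices are constrained to the *triangulated* graph, not
the moral graph: the clique machinery requires chordality, and fill-in edges
then act as free parameters. This is the one place where the fitted model is
slightly larger than the moral-graph model; the permutation calibration below
is unaffected because observed and permuted statistics use the same graph.

## Estimation when genes outnumber samples

Sample covariances with tens of genes and a handful of samples are singular,
so each covariance entering a fit is a James–Stein-type shrinkage estimate

$$ S^* = (1 - \lambda)\, S + \lambda\, \mathrm{diag}(S), $$

i.e. correlations shrunk toward zero with the analytically optimal intensity
$\hat\lambda = \sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij}) / \sum_{i \ne j}
r_{ij}^2$ clipped to $[0, 1]$, variances untouched. `shrink_covariance()`
exposes this estimator; the result is positive definite whenever
$\lambda > 0$, whatever the $P/n$ ratio.

The graph constraint is then imposed by **iterative proportional scaling**
(`ips_fit()`): starting from the diagonal model, cycle over the maximal
cliques, each step updating the concentration on one clique block so the
fitted covariance matches $S^*$ there, until no fitted entry moves by more
than `tol` (default `1e-8`; `max_iter` default 5000 sweeps). The fitted
concentration is exactly zero off the graph by construction. Cliques are
visited in junction-tree preorder — a perfect sequence — so on a decomposable
graph IPS converges in a couple of sweeps; the likelihood kernel
$\log\det K - \mathrm{tr}(K S)$ is non-decreasing across sweeps. The Gaussian
profile log-likelihood reported by `ggm_loglik()` drops the
$-(nP/2)\log 2\pi$ constant throughout, so only differences are meaningful.

## Step 1: permutation tests

All statistics are $-2\log$ likelihood-ratio statistics (or monotone
equivalents) and all p-values are permutation-calibrated with the add-one
estimator $p = (1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(B + 1)$, so
$p \ge 1/(B+1)$ and seeded streams give bit-identical results. Shrinkage
intensities are re-estimated inside every permutation (an honest null); a
single intensity per split, estimated from the pooled within-group data, is
shared by the two group estimates so the likelihood comparison of the three
matrices is not driven by jitter between independently estimated
intensities (with separate intensities that jitter dominated the statistic
and destroyed its power).

**Concentration test.** $T = 2[\ell_1(\hat K_1) + \ell_2(\hat K_2) -
\ell_0(\hat K_0)]$, with $\hat K_k$ the IPS fit for class $k$ and $\hat K_0$
the fit under a common concentration, computed on shrunken *correlation*
matrices constrained to $G$: the test compares the strength of the links, and
class means and marginal variances are nuisance parameters for it.

Its calibration is a **rotation test** rather than a raw label permutation.
Each class's samples are Helmert-rotated onto the orthogonal complement of
the class mean, giving $n - 2$ columns that are exactly iid $N(0, \Sigma_k)$
under Gaussianity whatever the class means are; the observed class
covariances computed from the rotated columns coincide with the unbiased
sample covariances, and the $B$ "permutations" shuffle rotated columns
between the two groups. Both obvious alternatives fail one requirement each:
permuting raw labels is exact under the complete null but loses essentially
all power against a concentration difference accompanied by a strong mean
shift (the shift leaks into the permuted within-group covariances and
inflates the permutation distribution); permuting class-centered residuals
is mean-invariant but residuals are not exchangeable (each class's residuals
sum to zero), which made the test measurably conservative. The rotation
scheme has both properties, at the price that exactness is model-based
(Gaussian) rather than distribution-free. Single-gene components use a
two-sample variance-ratio LRT on the rotated columns.

**Mean test.** Two variants, as the models may or may not share a covariance:
the homoschedastic statistic $\frac{n_1 n_2}{n} \delta' \hat K_w \delta$ with
$\delta$ the mean difference and $\hat K_w$ the common graph-constrained
concentration fitted to the pooled within-class shrunken covariance; and the
heteroschedastic (Behrens–Fisher analog)
$\delta' (\hat\Sigma_1/n_1 + \hat\Sigma_2/n_2)^{-1} \delta$ with
class-specific fits. Permutation calibration makes any monotone-equivalent
form of the LRT valid, so these quadratic forms are used directly. The
pipeline picks the heteroschedastic variant when the pathway's concentration
test rejects at $\alpha$, the homoschedastic one otherwise.

**Clique tests.** The same two tests run on every clique. Cliques are
complete subgraphs, so no IPS is needed: the statistic reduces to
$n \log\det S^*_p - n_1 \log\det S^*_1 - n_2 \log\det S^*_2$ on the clique
block (correlation scale, as above). The clique's concentration-test p-value
becomes its **weight** $w$; from here on $w$ is a score, not a probability. A
weight is *meaningful* when strictly below $\alpha$ (default 0.05).

Across pathways, mean and concentration p-values are Bonferroni-adjusted
within their own family; a pathway enters step 2 when both adjusted values
fall below $\alpha$ (configurable via `gating`).

## Step 2: mining signal sub-paths

A *path* is the junction-tree path from the root clique to a leaf. On each
path, candidate *sub-paths* are the contiguous segments that start and end at
meaningful cliques and contain at most one non-meaningful clique; both
granularities are kept when a single non-meaningful clique bridges two
meaningful runs (the bridged segment and each run). Scoring walks the
sub-path in order:

$$ o_i = o_{i-1} + (1 - 2 w_i), \quad o_0 = 0, \qquad r = \max_i o_i, $$

with $m$ the first position attaining the maximum, and the length-adjusted
**standardized relevance** $r^* = r / m$. A weight of 0.5 is neutral; small
weights push the running score up. Per path, the candidate with maximal
$r^*$ wins (ties: longer sub-path, then earlier start). All scoring formulas
live in a single `scoring_policy()` object, so an alternative convention —
different increment, standardization, or dissimilarity — replaces one code
site and every downstream result follows.

Winners from different paths overlap heavily (they share the segment near the
root), so they are collapsed: with gene sets $A, B$,

$$ d(A, B) = \min\!\left(\frac{|A \setminus B|}{|A|},
                         \frac{|B \setminus A|}{|B|}\right) \in [0, 1], $$

which is 0 for nested sets and 1 for disjoint ones. Hierarchical clustering
on $d$ is cut at height $t$ (default 0.2) and each cluster is represented by
its maximal-$r^*$ member. Single linkage is the default because it makes the
collapse rule exact: any two sub-paths with $d \le t$ end in the same
cluster, hence representatives are pairwise more dissimilar than $t$ —
average linkage (available via `method`) cannot guarantee that.

## The synthetic-data generator

`random_ggm()` instantiates $K \in S^+(G)$ by giving each edge a random
entry with magnitude uniform in $[0.1, 0.4]$ and random sign, then setting
the diagonal to the absolute row sum plus a conditioning margin (default
0.5), which by Gershgorin's theorem bounds the smallest eigenvalue from below
— zeros off the graph are exact. `sample_scenario()` draws the two classes
through the Cholesky factor of each $K$.

The default study conditions (`default_pathway_graph()`, `null_study()`) are
a 12-gene decomposable graph of five cliques
$\{g_{1..4}\},\{g_{4..6}\},\{g_{6..8}\},\{g_{8..10}\},\{g_{10..12}\}$ chained
by single-gene separators — so the junction tree is one five-clique
root-to-leaf path, long enough to host multi-clique sub-paths — with
$n_1 = n_2 = 20$ samples per class. Calibration uses 1000 runs at $B = 500$
permutations; these sizes give binomial 99% bands of about $\pm 1.7$
percentage points around a 5% rate while keeping a desk-scale run in the
minutes. Power and recovery checks (`alt_study()`,
`perturbed_scenario()`) flip the signs of the partial correlations inside two
target cliques (diagonal dominance makes the flipped matrix automatically
positive definite) and shift the target genes' means by 5 marginal standard
deviations, with $n_1 = n_2 = 50$.

What the generator emulates is exactly the model: Gaussian data whose
concentration matrix respects a known graph, with effects confined to chosen
cliques. What it does **not** emulate: probe-level noise, normalization
artifacts, heavy tails, outlying samples, batch structure, or pathway
annotation error. Passing calibration here therefore shows the tests are
exact under the model's exchangeability — it does not certify behaviour
under model misspecification on real data.

## Numerical choices and degenerate inputs

* IPS: `tol = 1e-8` on the largest fitted-covariance change per sweep,
  `max_iter = 5000`; a non-converged fit is flagged, and a permutation test
  aborts with a diagnostic if more than 1% of permutations fail to converge.
* Permutations: `B` defaults to 1000 (`sigpath()`), minimum 19; the same
  permutation stream drives every statistic of a pathway (common random
  numbers), and a master seed derives one sub-seed per pathway component and
  per simulation run, so any unit is independently reproducible.
* Ties: lexicographic everywhere in the topology pipeline (cycle edge,
  elimination order, Kruskal, MCS); first-maximum for the relevance position;
  longer-then-earlier for best sub-path; higher-$r$-then-first for cluster
  representatives.
* Degenerate inputs: zero-variance genes are rejected up front; single-gene
  cliques and single-gene pathways use the variance-ratio LRT; a pathway with
  no meaningful clique yields no sub-path (recorded, not an error); per-
  pathway failures in `sigpath()` are isolated, logged and skipped.

## Limitations

Topology is taken as fixed truth; errors in pathway curation propagate
silently. The concentration test reads link strength on the correlation
scale, so a pure marginal-variance change in a multi-gene clique is invisible
to it (the mean test and single-gene rule do not cover that case either).
Cycle breaking optimizes each cycle locally and has no global guarantee of
minimal edge removal. P-values are permutation-granular: with small $B$ the
attainable significance floor $1/(B+1)$ can exceed a Bonferroni-adjusted
threshold when many pathways are tested at once.
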