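---
title: "Auditing slow-fast alignment trimming: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing slow-fast alignment trimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

"Slow-fast" analysis removes the fastest-evolving alignment sites before
phylogenetic inference, on the premise that substitution saturation has
destroyed their signal. Whether that premise holds for deep phylogenies is
an empirical question: the probability that a site records a substitution
along a branch is roughly `rate x branch length`, so *slow* sites are
nearly blind to short internal branches — exactly the branches that matter
most in densely sampled trees of life. `slowfast` implements the machinery
to audit this trade-off: simulate protein alignments with known site rates
on a known tree, bin sites into substitution rate categories (SRCs), build
rate-specific alignment partitions (RSAPs), reconstruct bootstrap tree
samples per partition, and measure how recovery of reference bipartitions
depends on the site rate and the branch length.

## Substitution model and rate heterogeneity

Sites evolve under a reversible amino-acid CTMC. A model is a symmetric
exchangeability matrix $S$ plus equilibrium frequencies $\pi$, giving the
generator $Q_{ij} = s_{ij}\pi_j$ (rows summing to zero), rescaled so that
$-\sum_i \pi_i Q_{ii} = 1$: branch lengths are then expected substitutions
per site at the mean rate. LG, WAG, Dayhoff and JTT are built in (sourced
from the amino-acid model tables shipped with `phangorn`); arbitrary
PAML-layout `.dat` files are read by `read_paml_dat()`. Transition
probabilities use the spectral decomposition of the symmetrised generator
$\Pi^{1/2} Q \Pi^{-1/2}$ (real spectrum by reversibility), cached per
model, so $P(t)$ costs two 20x20 products at any $t$.

Across-site rate variation is the discrete-gamma approximation with $k$
equal-probability categories. Category rates are the **conditional means**
of a mean-1 Gamma($\alpha,\alpha$) within each quantile bin (the
mean-per-bin variant, not bin medians): with $\alpha = 0.803$, $k = 12$,
the rates run from $\approx 0.0234$ to $\approx 3.823$ and average exactly
1. The mean convention is used because the package's analytic worked
examples and the per-category expected-substitution arithmetic
(`expected_substitutions()`) are consistent with it; the median convention
gives a slowest rate several-fold smaller and does not average to 1.

## The synthetic-data generator

`run_simulation_study()` draws, per replicate:

* **Topology** — sequential random attachment: each new leaf is grafted
  onto a uniformly chosen existing edge, which makes every labelled
  unrooted binary topology equally likely.
* **Branch lengths** — independent gammas for internal and terminal
  edges, shapes 0.7581720 and 1.509421. The scales are calibrated from
  target *medians* (gamma quantile function): internal median 0.05
  substitutions/site, matching the short internal branches typical of
  densely sampled ribosomal-protein phylogenies. The terminal median
  defaults to 0.10 — terminal branches in such trees run longer than
  internal ones; this is a package calibration choice, settable through
  `branch_length_prior()`.
* **Sequences** — each site draws its category uniformly from the $k$
  equiprobable categories (the truth is recorded for recovery testing),
  the root state comes from $\pi$ (stationarity), and states propagate
  root-to-tips with per-branch transition probabilities at the site's
  category rate. No indels, no invariant class, no among-branch rate
  variation, no compositional drift.

What the generator deliberately does **not** emulate: alignment error,
gap structure, model misspecification across lineages, and compositional
heterogeneity. Consequences: gap-context classification
(`classify_gap_context()`) and the compositional-bias statistic
(`composition_sse()`) are exercised on synthetic fixtures and real data
only — passing tests on simulated data show the arithmetic is right, not
that misalignment behaves as it does in real alignments.

## Site-rate assignment and partitioning

Invariant columns (at most one distinct non-gap residue; gaps ignored) are
removed first and never receive a category. Each variable site then gets
an empirical-Bayes posterior over categories under a fixed guide tree,
$p_c \propto \frac{1}{k} L_{site}(r_c)$ (Felsenstein pruning, gaps as
missing data), and is hard-binned to the maximum-posterior category, ties
broken toward the slower category. On simulated data the guide tree is the
true tree; on real data it is user-supplied or the pipeline's own
ML-distance NJ tree. `estimate_alpha()` profiles the mixture likelihood
over $\alpha \in [0.05, 20]$ by bounded search; **all** columns enter that
likelihood, because under a model without an invariant class constant
columns are genuine slow-rate outcomes and dropping them biases
$\hat\alpha$ upward (we observed +0.35 on data simulated at 0.803).

Each category's sites form an RSAP by cyclic tandem replication to the
full alignment length, so every partition carries the same nominal number
of informative columns. Trimming schemes are fixed category sets:
slow = 1–4, fast = 10–12, both = their union (keeping 5–9).

## Tree estimation and bootstrap

Per bootstrap replicate, alignment columns are resampled with replacement,
all pairwise ML distances are re-estimated, and a neighbor-joining tree is
built (negative branch estimates clamped to zero). This classical
bootstrap over an ML-distance + NJ estimator replaces ML-search bootstrap
methods: it preserves the object the downstream statistics consume — a
sample of trees per partition — at desk scale, and externally produced
samples (multi-tree Newick) can be ingested with `read_tree_sample()`.

The pairwise distance maximises
$\sum_s \log \sum_c \frac{1}{k} \pi_{a_s} P_{a_s b_s}(r_c t)$ over
$t \in (0, 10]$. Numerical strategy: the per-cell log-likelihood table is
precomputed on a 192-point log-spaced grid shared by all pairs and
replicates; per pair, a stride-4 coarse scan plus a local fine scan finds
the grid optimum, refined by quadratic interpolation in $\log t$
(agreement with the exact one-dimensional optimiser is ~5e-4 on typical
pairs, far below bootstrap noise). Pairs whose optimum hits the bound are
capped at 10 substitutions/site and flagged saturated rather than
erroring — saturation is a studied condition here. Identical pairs return
exactly 0.

Inside the study, an RSAP's distances are estimated under a **single
homogeneous rate**, not the 12-category mixture: an RSAP is
rate-homogeneous by construction (the real-data analog refits the model
per partition). This matters for the fastest partitions — under the
mixture, slow components can absorb near-saturated divergences, flattening
the likelihood in $t$ and destroying deep-structure recovery; the
homogeneous likelihood restores it. The mixture grid remains the default
for rate-heterogeneous inputs (e.g., the audit's guide tree).

## Recovery statistics

A reference bipartition is *recovered* by a partition when it appears in
at least 80% of that partition's bootstrap trees (threshold configurable).
Reported per partition: the median branch length of recovered splits, the
fraction of below-median-branch reference splits recovered, and the
fraction of top-quartile-branch splits recovered (median and quartile over
the reference tree's internal branch lengths — bipartitions are internal
edges). Across partitions: Spearman correlations between mean category
rate and (i) the median recovered branch length and (ii) the pooled branch
lengths of recovered splits; Benjamini–Hochberg q-values control FDR
across simulation replicates; and the OLS slope of mean RF distance on
mean category rate over the fast categories (9–12 by default) quantifies
the saturation-driven deterioration at the fast end. Spearman p-values use
the exact permutation distribution below 10 pairs (t approximation with
ties) and the large-sample approximation otherwise. RF distances are
unnormalised symmetric differences of canonical split sets; classical
(Torgerson) MDS of the tree-to-tree RF matrix visualises the tree-space
region each partition explores.

## Problem sizes and reproducibility

The package's reference configuration mirrors the full design
(1000 leaves, 2596 sites, 100 replicates, 1000 bootstrap trees per
partition). The bundled analyses and tests run a desk-scale version —
100 leaves, 2596 sites, 3 replicate alignments, 100 bootstrap trees per
partition — which completes in a few minutes on one CPU and reproduces the
qualitative pattern: the slowest partition recovers the smallest fraction
of short-branched bipartitions and is farthest from the true tree, while
recovery of the longest branches is near-complete for all but the slowest
partition. One master seed fans out deterministically to per-stage,
per-replicate seeds (`topology`, `branch lengths`, `sequences`, one per
partition bootstrap), so any sub-experiment reruns in isolation and every
output table is bit-reproducible.

## Known limitations

* Distance-based NJ bootstrap pools information far less efficiently than
  ML tree search. At desk scale it reproduces the *ordering* of
  partitions but compresses absolute recovery fractions, most visibly for
  the slowest partition, whose variable sites carry very few substitutions
  tree-wide on a 100-leaf tree (total tree length is roughly a tenth of
  the 1000-leaf design, so the slowest category sees ~0.5 substitutions
  per site across the whole tree).
* Fixed-tree model selection scores candidates under homogeneous rates
  with BIC ($n$ = alignment length; empirical frequencies cost 19
  parameters); it does not search tree space.
* The gamma scales of the branch-length prior are calibrated, not
  estimated from data; audits of real alignments should check the
  resulting branch-length distribution against their own tree.
* No indel model: gap handling (missing data, gap-context labels) is
  implemented and tested, but gap *generation* is out of scope.
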