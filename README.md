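# slowfast

Tools for auditing the "slow-fast" alignment-trimming practice in deep
phylogenetics.

Slow-fast analysis removes the fastest-evolving sites of a protein
alignment before tree inference, assuming substitution saturation has
destroyed their signal. But the chance that a site records a substitution
along a branch scales with `site rate x branch length`, so slow sites are
nearly blind to the *short* internal branches that dominate densely
sampled phylogenies. `slowfast` lets you test which effect wins, on
simulated data where the true tree is known and on your own alignments.

The pipeline:

1. **Simulate** amino-acid alignments on random trees under a reversible
   model (LG/WAG/Dayhoff/JTT) with discrete-gamma rate heterogeneity —
   `k` equal-probability categories carrying the conditional mean rate of
   each quantile bin of a mean-1 Gamma(α, α); branch lengths drawn from
   separate internal/terminal gamma priors.
2. **Bin** sites into substitution rate categories (SRCs) by
   empirical-Bayes posterior under a fixed tree
   (p<sub>c</sub> ∝ (1/k) · L<sub>site</sub>(r<sub>c</sub>), Felsenstein
   pruning, invariant sites removed first).
3. **Partition**: tandem-replicate each SRC's sites to the full alignment
   length (rate-specific alignment partitions, RSAPs), or trim slow
   (SRC1–4), fast (SRC10–12), or both.
4. **Bootstrap** each partition: resample columns, re-estimate all
   pairwise ML distances under the model, rebuild a neighbor-joining
   tree.
5. **Score**: a reference bipartition is *recovered* when it appears in
   ≥ 80% of a partition's bootstrap trees. Report per-partition recovery
   of short-branched (below-median) and long-branched (top-quartile)
   splits, Robinson–Foulds distances to the reference, Spearman
   correlations of rate vs recovered branch length (BH-corrected across
   replicates), OLS slopes of RF on rate, tree-space MDS, and
   per-partition amino-acid composition bias (sum of squared frequency
   errors).

## Worked example

Why short branches are invisible to slow sites — the analytic arithmetic
for a 0.05 substitutions/site branch on a 2596-site alignment split into
12 rate categories at α = 0.803:

```r
library(slowfast)
g <- discretize_gamma(0.803, 12)
g
#> Discrete gamma rates: alpha = 0.803 , k = 12
#>  [1] 0.02337 0.08982 0.17540 0.27840 0.40060 0.54600 0.72120 0.93740 1.21500
#> [10] 1.59600 2.19400 3.82300

e1  <- expected_substitutions(0.05, 2596, 12, g$rates[1])
e12 <- expected_substitutions(0.05, 2596, 12, g$rates[12])
```

The branch carries `e1$total` = 129.8 expected substitutions in all.
The slowest category's 216.3 sites contribute `e1$count` ≈ 0.25 of them
(0.195% of the branch total) — essentially nothing to infer the split
from — while the fastest category contributes `e12$count` ≈ 41.36
(31.86%).

A small end-to-end simulation study (the full desk-scale configuration
used by the bundled analyses is 100 leaves × 2596 sites; this one runs in
under a minute):

```r
cfg <- experiment_config(n_leaves = 40, n_sites = 600, n_replicates = 2,
                         n_bootstrap = 50, seed = 42)
st <- run_simulation_study(cfg, verbose = FALSE)
st
#> Slow-fast simulation study: 2 replicates, 40 leaves, 600 sites
#>   mean pooled Spearman rho (rate vs recovered branch length): -0.065
#>   below-median-branch recovery: slowest 2.8%, fastest 30.6%
#>   minimum top-quartile recovery across categories: 70.0%
#>   RF to true tree maximal in category 2 , minimal in category 9
```

Reading the summary: the fastest partition recovers ~11× more
short-branched true bipartitions than the slowest (30.6% vs 2.8% at ≥ 80%
bootstrap support), the correlation between a partition's rate and the
branch lengths of what it recovers is negative (slow partitions only
recover long branches), and the trees closest to the truth come from the
mid/fast rate range — not from the slow sites that trimming would keep.

The numbered scripts under `analysis/` run the full set of analyses
(worked examples, desk-scale study, rate/α recovery, trimming audit with
MDS and composition, model selection, taxon subsampling) and write their
tables under `results/`.

## Auditing your own alignment

```r
audit <- run_audit("alignment.fasta", tree = "guide.nwk",
                   config = experiment_config(n_bootstrap = 200, seed = 1),
                   out_dir = "audit_out", mds = TRUE)
```

writes the trimmed alignments (FASTA), per-site rate table (TSV),
per-partition recovery and composition tables, and MDS coordinates of the
bootstrap tree space. Externally generated bootstrap samples (multi-tree
Newick, e.g. from ML-search software) can be scored through
`read_tree_sample()` + `compatible_reference_bipartitions()`.

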