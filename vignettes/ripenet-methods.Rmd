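---
title: "Methods: exact Poisson DE and weighted coexpression networks in ripenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact Poisson DE and weighted coexpression networks in ripenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripenet)
```

## The analysis problem

ripenet targets a common but statistically awkward design in fruit
genomics: one RNA-seq library per condition, no replicates, across a
two-genotype (wild type vs a late-ripening mutant) by three-stage
(170/190/210 days after flowering) grid.  The package covers the full
downstream path from a count matrix to biological summaries: differential
expression, transcription-factor (TF) family assignment, weighted
coexpression modules, module validation, module–trait association, and
set/cluster/enrichment analyses.  A seeded synthetic-data generator plants
known effects so that every stage can be tested offline against a ground
truth.

## Exact Poisson test for two libraries

With a single library per condition, the only replication is technical:
read sampling.  If a gene emits a small fraction of a library of `N` clean
reads, its count `x` is well modelled as Poisson with unknown rate
proportional to its true transcript abundance.  For counts `x` in library 1
(size `N1`) and `y` in library 2 (size `N2`), marginalizing the shared rate
gives the conditional distribution

$$P(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

a negative-binomial-shaped function of `y`.  The two-sided p-value doubles
the lower cumulative $C=\sum_{i=0}^{y}P(i\mid x)$: $p = 2C$ when
$C \le 0.5$ and $p = 2(1-C)$ otherwise, capped at 1.

Two numerical choices matter:

* **Log-space evaluation.** Every term is computed via `lgamma` and
  accumulated with log-sum-exp, so counts up to $10^6$ and beyond neither
  overflow nor underflow (`ac_test_pvalue`).
* **No "one minus".** When $C > 0.5$, $1-C$ is itself a sum of tail terms
  and is computed by summing $P(i\mid x)$ for $i > y$ directly, in chunks,
  with a geometric bound on the truncated remainder.  Computing `2*(1-C)`
  from the lower sum loses all precision once $C$ is within a few
  double-precision ulps of 1 — in double arithmetic it can even go
  negative — so the tail is never derived by subtraction.

The doubled tail includes the observed point mass `P(y|x)`, so the rule is
slightly asymmetric around the point probability.  This literal
construction is retained deliberately rather than replaced by a
minimum-likelihood or mid-p variant, because it is the form the test is
conventionally quoted in; its effect is conservative.

The test's assumptions are honest limitations: it models technical
(sampling) variance only.  Biological replicate variance is invisible to
it, and under overdispersed counts it is anti-conservative — the generator
has an explicit negative-binomial mode (`dispersion` argument of
`generate_counts`) whose only purpose is to demonstrate that failure mode
in the test suite.  No replicate-aware model is attempted.

### DEG calling

A gene is differentially expressed when `FDR <= 0.001` and
`|log2 ratio| >= 1`.  The FDR is Benjamini–Hochberg, applied **per
pairwise comparison** (each mutant-vs-wild-type stage pair is its own
multiple-testing family); pooling the three stage comparisons into one
family is the other defensible reading, and per-comparison was chosen as
the default because each stage pair is reported as a separate contrast.

### Fold changes and the RPKM floor

Expression is normalized as RPKM, $10^9 x / (N L)$ for gene length `L` bp.
Fold changes are `log2(max(mt, floor) / max(wt, floor))` with
`floor = 0.001` RPKM: the floor substitutes only for values below it, so
any ratio of two quantified values is exact.  The value 0.001 was chosen
because stage-wise tables in this literature report fold-change magnitudes
near 10 for genes quantified on one side only (e.g. an RPKM of 1.31
against an absent value gives $\log_2(0.001/1.31) \approx -10.4$), which a
floor of 0.001 reproduces; it is exposed as a parameter since the
convention is not standardized.

## TF family assignment

Family assignment consumes a precomputed domain-hit table (gene, model,
e-value, score) — running the profile-HMM search itself is out of scope —
plus a rule table in the required/forbidden style of plant TF databases: a
family claims a gene when all its required DNA-binding-domain models are
hit and none of its forbidden models is.  Hits with e-value above `1e-10`
are discarded first.  When several families qualify, the family whose best
supporting hit has the smallest e-value wins; ties break by larger score,
then lexicographic family name, making assignment deterministic and
invariant to hit order.  The shipped rule table
(`default_family_rules()`) is a small illustrative subset and is meant to
be replaced by a database-derived table in real use.

## Weighted coexpression network

The network follows the standard unsigned weighted construction:

1. **Filter**: keep genes whose **maximum** RPKM across samples exceeds
   0.3.  The max (rather than mean) is used so genes expressed in only one
   stage or genotype survive; a mean-based filter is available.
2. **Adjacency**: $a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$ on
   `log2(RPKM + 1)` profiles, diagonal zero.  The soft power defaults to
   $\beta = 6$, the conventional unsigned default; `pick_soft_threshold`
   scans candidate powers and returns the smallest whose scale-free fit
   index (signed $R^2$ of the log–log connectivity regression, 10
   equal-width bins) reaches 0.8, falling back to the best-fitting power
   with a warning when none does.
3. **Topological overlap**:
   $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
   (\min(k_i,k_j) + 1 - a_{ij})$, diagonal 1.  `1 - TOM` is the clustering
   dissimilarity.
4. **Modules**: average-linkage hierarchical clustering, then a simplified
   tree cut: a grid of 50 fixed cut heights (quantiles of the merge
   heights) is scanned and the cut that yields the most branches of at
   least `min_module_size = 30` genes wins (ties: more genes assigned,
   then the lower height).  Genes outside qualifying branches are grey.
   Modules whose eigengene dissimilarity (1 − correlation) is below
   `merge_cut_height = 0.25` merge iteratively, closest pair first, until
   stable.  Finally, genes whose module membership `|kME|` to their own
   module falls below 0.5 are released to grey.  The pruning level is the
   core-membership convention — a retained gene shares at least a quarter
   of its variance with its module eigengene.  It matters: a fixed-height
   cut assigns *every* gene to some branch, and with several latent
   factors, the best-of-k correlation of an unrelated gene frequently
   lands in the 0.3–0.6 range at moderate sample counts, so a laxer
   threshold would keep substantial noise inside modules.
   This whole procedure approximates the dynamic hybrid tree cut; only
   the minimum-size and merge-height parameters of the original are
   honoured, which is the level of detail at which such analyses are
   usually reported.
5. **Single block**: the block-size limit (default 19000) is an error
   bound, not a partitioning scheme — multi-block pre-clustering is not
   implemented, since at the intended scale the limit exceeds the filtered
   gene count and blocking never triggers.

The **module eigengene** is the first principal component of the module's
per-gene-standardized expression, rescaled to unit sample variance, with
the sign chosen so its mean correlation with member genes is non-negative
(determinism for testing; SVD signs are otherwise arbitrary).  kME (module
membership) and GS (gene significance) are plain Pearson correlations of
genes with eigengenes and traits; all correlation p-values use the Student
t transform with n − 2 degrees of freedom.  At the study-like scale of 6
samples these p-values are fragile — a |r| of 0.81 is needed for p < 0.05
— which is why the recovery-oriented tests run at 20 samples and why
results at n = 6 should be read as descriptive.

**Module–trait association** declares a module–trait (or module–TF) pair
significant at `|r| > 0.8` and `p < 0.05`; **hub screening** requires
`|GS| >= 0.8` with `p < 0.05` *and* `|kME| >= 0.8` with `p < 0.05` for the
gene's own module.

**Permutation validation**: a module is supported when its mean
intramodular topological overlap exceeds that of random same-size gene
sets.  The null resamples `B` sets uniformly without replacement (seeded);
the empirical p-value `(1 + #{null >= observed})/(B + 1)` can never be 0,
and equals `1/(B+1)` when the observed value beats every draw.  `B = 999`
is used for validation-grade runs (p resolution 0.001) and smaller `B` for
routine pipeline runs.

## Downstream summaries

* `venn_partition` gives exact disjoint-region counts for 2–3 gene sets;
  inclusion–exclusion holds by construction.  More than 3 sets is refused
  (a membership table is the right report there).
* `cluster_fc_profiles` clusters gene × stage log2-ratio profiles with
  **uncentered correlation** similarity and average linkage — the Eisen
  convention for expression patterns, which distinguishes sign-opposed
  profiles that centred correlation would conflate — cut to exactly `k`
  clusters labelled I..k in dendrogram order.  `k` defaults to 6 as an
  exposed parameter: the cluster count is an outcome one chooses when
  inspecting the tree, not a modelling constant.  All-zero profiles are
  rejected (their uncentered correlation is undefined) and missing fold
  changes must be imputed upstream, which the floored `log2_ratio` already
  guarantees.
* `hypergeometric_enrichment` is a one-sided upper-tail
  over-representation test per term with BH correction across terms and an
  enrichment cutoff of corrected p < 0.01.  BH is assumed for the
  correction because the upstream tools in this space do not document
  otherwise.

## Synthetic data: what it does and does not emulate

`generate_counts` draws `x_gs ~ Poisson(lambda_g * m_gs * N_s / 1e6)` with
log-normal base rates (median 20 reads per million, sdlog 1.3 — a
realistic dynamic range for a fruit transcriptome), planted DE multipliers
`2^(±effect)` applied to all mutant samples, and uniform gene lengths of
0.3–5 kb.  The desk-scale preset is 2,000 genes and 6 samples at library
size $10^6$ — the study shape at roughly one-tenth gene scale.
`generate_coexpression` plants modules from standardized latent factors:
member profile `loading·f_m + sqrt(1-loading^2)·e`, so within-module
correlation is `loading^2` in expectation (0.81 at loading 0.9), with
linked traits `f_m + N(0, 0.3^2)`.  `generate_domain_hits` emits
sub-cutoff hits for true TFs, suppresses a `miss_rate` fraction and adds
above-cutoff decoys.

All generators are deterministic under a seed (`with_seed` restores the
caller's RNG state) and record their truth — planted effects, memberships,
factors, trait links — for recovery scoring.

What the generators deliberately do **not** emulate: read-level artefacts
(mapping bias, multi-mapping, GC effects), correlated gene lengths and
expression, compositional library effects, and biological replicate
variance (except through the labelled NB mode).  Passing recovery tests on
this synthetic structure therefore demonstrates the correctness of the
implemented statistics, not robustness of the pipeline to everything real
data can do.

## Problem sizes and determinism in the shipped checks

The test-suite and acceptance-script workloads were sized to exercise each
property at meaningful precision while staying quick on a laptop: the
exact-test/direct-summation sweep covers all counts up to 200 at library
ratios 0.5/1/2 (121,203 p-values); null calibration uses 10,000 genes;
power uses 200 planted 4-fold effects at rate 100; module recovery uses
the 5-module, size-50, loading-0.9, 20-sample preset with `B = 999`
permutations; trait-link recovery uses 100 seeded replicates.  All
randomness passes through explicit seeds, and the pipeline writes a JSON
manifest (parameters, seed, per-stage row counts) sufficient to reproduce
a run bit for bit from the same inputs.

## Known limitations

* No replicate-aware dispersion modelling; the exact test is valid for
  technical sampling only.
* The simplified tree cut is not the dynamic hybrid algorithm; very close
  or nested modules that the hybrid cut separates may merge or prune
  differently here.
* Correlation p-values at 6 samples are fragile by construction; module
  counts at full study scale are not expected to be reproduced without
  the original data.
* The shipped TF rule table is illustrative; family calls are only as
  good as the rule table supplied.
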