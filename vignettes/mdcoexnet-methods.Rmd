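---
title: "Methods: multi-dimensional co-expression network analysis"
author: "mdcoexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-dimensional co-expression network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcoexnet)
```

## Scope and model

`mdcoexnet` analyses bulk RNA-seq FPKM matrices sampled across
heterogeneous conditions — multiple tissues and developmental stages
plus paired stress/control samples, the design typical of plant
transcriptome compendia (a few dozen samples, no or few replicates per
stress condition). Its stages are:

1. an expression threshold separating expressed from unexpressed genes,
2. a signed, tiered Mutual-Rank (MR) co-expression network,
3. tissue-preferential and stress-differential state overlays,
4. overlapping functional-module detection by k-clique percolation,
5. permutation Z-score enrichment of promoter cis-elements,
6. Fisher-exact term enrichment with FDR control, and
7. reciprocal-BLAST orthologue calling.

A seeded synthetic-data generator emits inputs with known planted
structure so every stage is testable end to end without external data.

## Expression threshold

For each experimental group the per-sample lower 5% tails of FPKM
values are pooled and the threshold is `mean(pool) + 3 * SD(pool)`
(sample SD). Two points are under-determined by this recipe and are
explicit package choices:

* **What the SD is taken over.** We pool each group's per-sample tail
  values and take the SD of the pool. Both the quantile (default 0.05)
  and the multiplier (default 3) are arguments.
* **Aggregation across groups.** Per-group thresholds are combined by
  `min` by default — it is a *minimum* expression threshold — with
  `max` and `mean` selectable.

The quantile is the linear-interpolation (type 7) quantile of the
sorted per-sample values; the tail is every value at or below it. A
pooled tail smaller than two values has its SD treated as 0, with a
warning. Missing values are not supported: absence must be encoded as
0 upstream.

## The Mutual-Rank network

Pearson correlation (PCC) is computed on the FPKM values across the
chosen samples. For each gene, partners are ranked twice: descending
PCC (positive direction) and ascending PCC (negative direction); the
Mutual Rank of a pair is the geometric mean of its two directional
ranks, `MR = sqrt(rank_ab * rank_ba)`. Candidate pairs must pass the
sign-appropriate PCC cutoff — defaults +0.65 for positive and −0.45
for negative pairs, with a percentile mode (95th/5th percentiles of
the all-pairs PCC distribution) available — and are retained when
`min(rank_ab, rank_ba) <= 3` **or** `MR <= 30`. Retained edges are
tiered `rank_top`, `mr_le_5`, `mr_le_30`.

Interpretation choices, all configurable:

* "Single-direction rank less than 3" is read inclusively
  (`min rank <= 3`), consistent with a *top-3* tier that contains
  rank 3.
* Retention is the **union** of the rank rule and the MR rule; the
  three tiers otherwise could not all be populated.
* Negative pairs get their own ascending-PCC ranking. Ranking by
  |PCC| is the other defensible reading; the ascending convention is
  symmetric with the positive direction and is what the tests pin
  down.
* Rank ties are broken lexicographically by gene id, so ranks are a
  permutation and network construction is fully deterministic.
* Genes with zero variance across the chosen samples are excluded
  before ranking (PCC undefined); the count is reported.
* Network nodes are the genes incident to at least one retained edge.

Sub-networks select a seed neighbourhood filtered by edge sign;
network comparisons count shared nodes and sign-qualified shared
edges, with per-network overlap ratios and an edge Jaccard index.

## Expression-state overlays

A gene is *expressed* in a tissue when its mean FPKM over that
tissue's samples exceeds the threshold (strictly). For a stress
treatment versus its control in one tissue, a gene below threshold in
both conditions is *not expressed*; otherwise it is *up* when the
floored log2 fold change is ≥ 1 and *down* when ≤ −1 (inclusive
boundaries), else *unchanged*. The fold-change floor defaults to the
expression threshold, so ratios are never taken against zero.

Differential calling between two multi-sample classes uses the Welch
(unequal-variance) two-sided t-test with Benjamini–Hochberg FDR and a
|log2FC| cutoff (defaults 0.05 and 1 — the tight cutoffs a typical
analysis would report; both are arguments). The test is applied to
`log2(max(FPKM, floor))` by default: on the log scale the noise is
approximately Gaussian with stable variance across genes, which is
what a t-test assumes; `logTransform = FALSE` tests raw FPKM. Stress
conditions without replicates use the fold-change-only overlay rule;
the t-test path applies to replicated class comparisons only.

## Module detection by clique percolation

Communities are defined by the standard clique-percolation rule: two
k-cliques are adjacent when they share k−1 nodes; communities are
connected components of the clique graph, and a community's members
are the union of its cliques. Communities may overlap. The default
clique size is k = 6. The informal gloss "each node interacts with at
least six nodes in a module" overstates the guarantee — a k-clique
member has k−1 neighbours inside its clique — and the standard
definition is what is implemented and oracle-tested.

Implementation note: clique adjacency is found by hashing each
clique's (k−1)-subsets — two distinct k-cliques share k−1 nodes
exactly when they share such a subset — so percolation needs no
pairwise clique comparison. Equivalence with a literal brute-force
oracle (enumerate subsets, chain by overlap) is asserted on random
graphs up to 25 nodes for k in 3..6.

CPM runs on the union of positive and negative edges by default:
a module with anti-correlated members is one regulatory unit, and the
sign-agnostic reading keeps such members in one community. A
`positive_only` mode restricts cliques to positive edges. Two modules
are *linked* when at least 3 distinct nodes of one are shared with, or
have a network edge into, the other (the larger of the two per-side
counts is reported; the source phrasing "three nodes connected to
other modules" does not fix a side). `cpmParameterReport()` tabulates
module count, gene coverage and community overlap across k, the
quantities used to choose the clique size.

## Cis-element enrichment

Promoters are the `length` (default 3000) bases upstream of the
transcription start on the coding strand, truncated at sequence
boundaries, extracted from a genome FASTA plus GFF3 or supplied
directly as FASTA. Motifs are IUPAC strings; matching expands
ambiguity codes in the motif, counts overlapping start positions, and
scans both strands, de-duplicating by (start, matched pattern) so a
palindromic motif counts once per position.

The enrichment statistic for a gene list is the summed motif count
over the list's promoters. The null is built from 1000 (configurable,
minimum 100) random lists of the same size drawn uniformly without
replacement from the background; `Z = (s − mu) / sigma` with `mu` and
`sigma` the mean and sample SD of the null sums, and p the one-sided
upper-tail normal probability. Two choices deserve note: the source
description of sigma ("SD of the 1000 mean value") is self-inconsistent
and is implemented as the SD of the null *sums*; and p is one-sided
because depletion is not of interest in this workflow. Random lists
are not matched for GC or length; the background defaults to all
genes with promoters. `sigma = 0` (constant null) degenerates to
p = 1 or 0 with a warning.

Term enrichment is a one-sided Fisher exact test per term on the 2×2
list/background table, with Benjamini–Yekutieli adjustment by default
(dependence-robust, matching the workflow's convention for annotation
terms) and significance at q ≤ 0.05.

## Orthologue calling

From bidirectional tabular BLAST results (outfmt 6), *best* pairs are
those where each gene is within the other's top 3 hits; *secondary*
pairs are reciprocal hits with both e-values < 1e-55 that are not
best. Ranks count distinct subjects per query — multiple HSP lines for
one subject collapse to their best e-value — ordered by ascending
e-value, then descending bitscore, then subject id. Whether the
e-value rule requires one or both directions is not fixed by its
source; both directions is the default (consistent with
"bidirectional"), one-directional is available. Running BLAST itself
is out of scope; IDs are used verbatim.

## The synthetic-data generator

`generateExpression()` emulates the 29-sample study layout: six
tissues across developmental stages (23 samples without stress) plus
root, stem and leaf each under control, PEG and NaCl (9 stress
samples). Expression is log-normal-like: FPKM = 2^x where x is a
per-gene baseline (N(3, 1)) plus noise (SD 0.25 by default) and, for
planted module members, ± a latent per-sample module activity
(N(0, 1)). Module activities are orthogonalised across modules (QR)
so each planted module is a distinct latent factor and the emitted
truth labels are identifiable; 20% of members load negatively.
Planted DEGs add a stated log2 effect (default 2, a 4-fold shift) in
designated samples. Defaults: 1000 genes, 10 modules of 15.

What the generator does *not* emulate: count-based sampling noise
(mean–variance coupling at low expression), batch effects, correlated
background gene programs, isoform ambiguity, or realistic promoter
base composition (promoters are i.i.d. uniform ACGT with Poisson
planted motif insertions; BLAST tables are rank-structured decoys).
Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under a clean generative model, not robustness
to every artefact of real RNA-seq.

## Validation suite and problem sizes

The validation suite (see `tests/testthat/test-acceptance.R`) checks,
at the sizes the package documents as its standard validation
conditions: MR exactness and bounds (10,000 random rank pairs);
equality of network construction with a literal brute-force
implementation (50 matrices of 20–40 genes); CPM equality with a
brute-force oracle (200 random graphs, n ≤ 25, k ∈ 3..6);
planted-module recovery on the 1000-gene default simulation; null
calibration (200 repetitions) and planted power (100 repetitions) of
the permutation Z-test at list size 50 over a background of 500;
DEG null control and recovery (1000 genes, n = 4 per class);
step-up adjustment against brute force (1000 vectors); Fisher p
against hypergeometric tails (all tables over small backgrounds plus
random tables with margins ≤ 30); orthologue rules against brute
force (100 synthetic tables); and byte-identical pipeline re-runs.

One check is known to sit below its target under these conditions:
planted-module recovery. With 29 samples the null PCC distribution
has SD ≈ 1/sqrt(27) ≈ 0.19, so the −0.45 negative cutoff lies at
about 2.4 SD: roughly one background gene in 200 anti-correlates with
a given module's activity strongly enough to acquire five or more
retained negative edges into it, form mixed 6-cliques, and join the
community. Each planted 15-gene module therefore accretes a few such
passengers, and the mean best-match Jaccard between planted and
recovered modules settles near 15/(15+4) ≈ 0.78 rather than above
0.8. This is a property of the fixed cutoffs at this sample size, not
of the clique-percolation implementation (which is brute-force
exact); scanning `cpmParameterReport()` or raising the negative
cutoff removes the passengers at the cost of departing from the
published parameterisation.

## Numerical and reproducibility choices

* All stochastic steps (generators, permutation tests) take explicit
  seeds and restore the caller's RNG state.
* Rank ties and module ids are resolved lexicographically; outputs
  are sorted, so identical inputs yield byte-identical files.
* The pipeline manifest echoes the full configuration, seeds, package
  version and per-stage record counts; re-running with the same
  manifest configuration reproduces the run exactly.
* Degenerate inputs fail loudly (zero-variance genes, constant
  t-test groups, empty tails, sigma-zero nulls) rather than silently
  propagating NaN.

## Limitations

* PCC is computed on linear FPKM, following the published method; on
  log-normal data this is outlier-sensitive. A log-scale correlation
  option would change the published semantics and is deliberately not
  provided.
* The stress overlay uses single-sample fold changes when no
  replicates exist — descriptive, not inferential.
* k-clique enumeration is exponential in dense graphs; the percentile
  cutoff mode can produce dense candidate sets on synthetic data and
  is intended for exploring cutoffs, not for routine module
  detection.
* The normal approximation for the permutation Z-test p-value relies
  on the null sums being approximately Gaussian; for very small lists
  or sparse motifs the empirical permutation p would be preferable.
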