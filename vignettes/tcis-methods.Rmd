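---
title: "tcis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alternative splicing shifts which isoform of a gene is predominantly
expressed. In a time course, such an *isoform switch* (IS) appears as an
intersection of two isoforms' relative-abundance curves: the isoform that
dominated early is overtaken by another. Unlike differential isoform
expression, which tracks one isoform's level, IS detection asks *which*
isoform carries the gene's output at each time, and therefore speaks
directly to functional consequences (e.g. protein-domain gain or loss
between the old and new dominant isoform).

`tcis` detects and scores IS events in an isoform-by-sample expression
matrix (TPM or counts) with an ordered time axis and a fixed number of
replicates per time point, clusters the affected genes by their temporal
splicing behaviour, relates them to candidate splicing-factor regulators,
and ships a fully ground-truthed simulator plus a precision/recall
harness so every claim about the detector can be measured.

## Relative abundance and switch points

For isoform $i$ of gene $G$ in sample $s$, the relative abundance is
$I_{i,s} = x_{i,s} / \sum_{j \in G} x_{j,s}$, the isoform's share of its
gene's expression; genes entirely unexpressed in a sample get shares of 0
(not NaN) and are skipped at those points. Transcripts with mean TPM
below 1, pooled over all samples, are removed before detection. The mean
is pooled rather than per time point because the filter's purpose is to
drop transcripts that are noise everywhere, not to censor transient
expression.

A *switch point* for an isoform pair is a time interval $(t, t+1)$ in
which the sign of $I_a - I_b$ changes in at least 60% of the replicates
(any sign change when there is a single replicate). An exact tie at a
time point is assigned to the earlier interval, so a curve that touches
and crosses is counted once. Both choices follow the rule "curves
intersect in enough replicates"; the support threshold is configurable
(`min_support`).

## Event metrics

Each candidate switch point $s$ of a pair $(i, j)$, with pre-interval
$T_1$ (from the previous qualifying switch point, or the series start, up
to $s$) and post-interval $T_2$ (from $s+1$ to the next qualifying switch
point, or the series end), is scored with:

* **Switching probability** — the average of the frequency of samples in
  $T_1$ where $I_i > I_j$ and of samples in $T_2$ where $I_i < I_j$;
  1 for a clean, sustained switch, about 0.5 for noise.
* **Difference of relative abundance** —
  $\big(|\overline{\Delta I_i}| + |\overline{\Delta I_j}|\big)/2$ where
  $\overline{\Delta I}$ is the replicate-mean change between $s$ and
  $s+1$. The absolute value is taken per isoform: the two isoforms move
  in opposite directions, and without it the terms would cancel rather
  than add up to a magnitude.
* **Event importance** — the mean, over replicates and the two flanking
  time points, of the two isoforms' abundances normalized to the highest
  isoform abundance of the gene at the same time point and replicate.
  Near 1 when the gene's dominant isoforms switch, near 0 for switches
  between minor isoforms. This is the metric that downweights
  transcriptional noise from lowly expressed isoforms.
* **Dissimilarity coefficient** — $d = 1 - r^2$ with $r$ the Pearson
  correlation of the two replicate-averaged courses. Note that this form
  maps *both* perfectly correlated and perfectly anti-correlated courses
  to 0, although the anti-correlated pattern is the signature of a clean
  switch; `dissimilarity_method = "half_one_minus_r"` provides
  $d = (1-r)/2$, which maps anti-correlation to 1. We keep $1 - r^2$ as
  the default for fidelity to the published definition but set no store
  by it as a filter: see the threshold discussion below.

## Significance

With replicates, the per-sample differences $I_i - I_j$ before versus
after the switch point are compared with a two-sided Mann–Whitney U test.
A genuine switch flips the sign of this difference, so the pooled
difference is the natural statistic; it also proved markedly more
powerful than testing each isoform separately and combining
conservatively (which halved benchmark recall).

With a single replicate, a permutation test is used. Two design points
matter, and both were chosen after measuring the alternatives:

1. **The time axis is permuted jointly** (the same reordering applied to
   both courses). Permuting each course independently destroys the
   compositional anti-dependence between isoform fractions, and the
   resulting null p-values are strongly anti-conservative (12–46% below
   0.05 in simulations). The joint permutation is the
   exchangeability-respecting scheme and yields calibrated p-values.
2. **The binding statistic is the interval-mean difference** of the pair
   across the best crossing of the (permuted) courses, not the local
   jump between two adjacent time points. The local jump is essentially
   permutation-invariant in distribution — a scrambled step course has
   *more* large adjacent jumps, not fewer — and gives the test no power.
   The sustained separation that scrambling destroys is what
   distinguishes a switch.

The dissimilarity clause of the published criterion is retained but is
an exact tie under a joint permutation (Pearson correlation is
order-invariant). The p-value uses the add-one correction
$(b+1)/(n+1)$ with $n = 999$ permutations by default.

Per isoform pair, the switch point with the smallest p-value represents
the pair (ties: larger difference of relative abundance, then earlier
interval); other individually significant switch points are reported as
secondary. The representative p-values are corrected for multiple
testing over *all* pairs in the run (Benjamini–Hochberg by default; Holm
and Bonferroni available), which controls the FDR over reported events.

## Thresholds

Reported events must reach every configured threshold (inclusive):
replicate support ≥ 0.6, switching probability ≥ 0.5, difference of
relative abundance ≥ 0.2, event importance ≥ 0.3, dissimilarity ≥
`min_dissimilarity`, adjusted p < 0.05. The dissimilarity default of 0.5
mirrors the published real-data filter, but with $d = 1 - r^2$ it
excludes exactly the strongly anti-correlated pairs a switch produces;
the benchmark and the acceptance harness therefore run with
`min_dissimilarity = 0` (the operating point the benchmark protocol
itself enumerates), and users who want a dissimilarity filter are
pointed to `half_one_minus_r`. Raising any threshold can only remove
events (a property the test suite checks).

## The simulator: a stated world

The benchmark generator makes every assumption explicit:

* **Isoforms per gene**: Poisson with rate 3 (clamped to ≥ 1); about 20%
  of genes end up with a single isoform and act as non-switching
  background. Three isoforms per gene is a realistic central value for
  expressed mammalian genes.
* **Hidden states**: each multi-isoform gene carries a two-state
  (unswitched/switched) first-order Markov chain over the T time points,
  starting unswitched, with flip probability 0.1 per step in each
  direction by default (the benchmark's free parameter; the published
  protocol does not state it). A gene is a ground-truth switching gene
  iff its state flips at least once.
* **Abundances**: one Dirichlet draw per gene. Model 1 (switches among
  dominant isoforms) uses concentration 1 for background isoforms and
  $10\cdot(1, 2, \dots, s)$ for the $s$ designated switching isoforms
  (default $s = 2$); the switched state swaps the two
  highest-concentration isoforms. Model 2 uses $10\cdot(1,\dots,k)$ over
  all $k$ isoforms and swaps a uniformly random pair among isoforms with
  drawn abundance > 0.3, falling back to the two largest so every truth
  gene remains switch-capable.
* **Counts**: the expression of isoform $i$ at time $t$ is normal with
  mean $\mu_i = $ abundance $\times$ gene mean and variance drawn once
  per (isoform, time point) from Gamma(shape $= \mu_i + \nu$, scale
  $= \nu$), $\nu$ the noise level (1, 5 or 10), truncated at zero. The
  published variance formula is typographically garbled; this
  parameterization preserves its two stated properties — variance grows
  with abundance and with the noise level — and is isolated in one
  function. Expected variance is $(\mu_i + \nu)\nu$, i.e. a coefficient
  of variation of roughly $\sqrt{\nu/\mu_i}$.
* **Gene means**: log-normal, median 500, sdlog 1 (about 90% of genes
  between 100 and 2600). The published benchmark samples gene-level
  *count* means from a negative-binomial fit to a real dataset; a
  median of several hundred counts with a ten-fold spread is the scale
  of moderately-to-well-expressed genes in a typical bulk RNA-seq
  library and requires no external download. On this scale the three
  noise levels span CVs of roughly 4% to 30% for a median gene.
* **Reproducibility**: a per-gene RNG substream is derived from the seed
  so that enlarging `n_genes` leaves the earlier genes bit-identical.

What a green benchmark establishes — and what it does not: the simulator
produces step-like abundance changes with exchangeable replicate noise.
It does not emulate autocorrelated drift, library-size artefacts,
isoform-quantification uncertainty (bootstrap variance from the
quantifier), or gradual switches spread over several intervals. High
precision/recall here means the detector recovers planted, sustained
swaps under replicate noise; performance on slow switches or on data
with correlated errors is not certified by these tests. The noiseless
recall ceiling at the diff ≥ 0.2 operating point is the Dirichlet tail
$P(|p_a - p_b| \ge 0.2) \approx 0.75$ under Model 1 — the filter itself,
not the detector, bounds recall there.

## Total isoform usage and clustering

Per gene, the change of total isoform usage between consecutive time
points is the L1 distance between the gene's isoform-fraction vectors,
$\Delta_t = \sum_A |I_A(t+1) - I_A(t)| \in [0, 2]$, computed on
replicate-mean fractions (the published definition is silent on
replicate handling; averaging first matches how the courses are plotted
and tested). A complete two-isoform flip attains the upper bound 2.

Genes (by default the detected IS genes) are clustered on their
$(T-1)$-length usage-change profiles with Ward-linkage agglomerative
clustering, k-means, k-medoids (PAM), DBSCAN or OPTICS, under euclidean,
Pearson ($1 - r$) or dynamic-time-warping distances. The number of
clusters is deliberately manual for the partitional methods —
`ward_merge_heights()` prints the top merge heights to support the
choice — because cluster counts in usage profiles are dataset-specific.
Each cluster is summarized by its prototype, the coordinate-wise median
of member profiles, which is robust to the occasional extreme profile.

## Splicing-factor analysis

Candidate regulators are screened in two steps. First, co-expression:
Pearson correlation between each splicing factor's replicate-mean
expression course (factors must have TPM > 1 at every time point) and
each switching isoform's abundance course, keeping pairs with |r| > 0.7
and BH-adjusted correlation-test p < 0.05. Second, motif enrichment:
exon flanks (default 50 nt each side of the 5' and 3' boundaries,
excluding each isoform's first and last exon, minus-strand flanks
reverse-complemented) are scanned with log2-odds PSSMs; for each motif a
score threshold is calibrated so that the probability of a hit under the
background nucleotide distribution is below 0.01, using an exact dynamic
program over a discretized score lattice (step 1e-3, with the threshold
shifted up by the maximal rounding error so the exact-score bound still
holds — verified in the tests by exhaustive enumeration of all words up
to motif length 8). Above-threshold scores in lost and gained exon
flanks are compared with those in unregulated exons by a one-sided
Mann–Whitney U test, per motif and boundary.

"Lost" and "gained" exons are the internal exons present in only one of
the event's two isoforms (by genomic coordinates); "unregulated" exons
are the pair's shared internal exons plus internal exons of the gene's
other isoforms. The published analysis names the three categories
without defining the third precisely; this definition keeps the
comparison within the same genes.

## Numerical and degenerate-input choices

* Thresholds are inclusive (≥); the published text uses strict
  inequalities, which differ only on a measure-zero boundary.
* Zero-variance courses make the dissimilarity undefined; such pairs are
  excluded (counted in a single summary warning).
* Genes unexpressed at a flanking time point of a switch make event
  importance undefined; the switch point is skipped likewise.
* Mann–Whitney tests fall back to 1 with a warning when one side has
  fewer than two samples.
* Fewer than two above-threshold motif scores on either side of an
  enrichment comparison yield NA rather than a p-value.
* Switch intervals are 1-based in the R API: interval $s$ lies between
  time points $s$ and $s+1$.

## Known limitations

* Only pairwise switches are modelled; a coordinated rotation among
  three or more isoforms is reported as its pairwise projections.
* The permutation test assumes exchangeable time points under the null;
  strong temporal autocorrelation without a switch will inflate its
  false-positive rate.
* The PSSM scan models direct binding only; factors binding through
  adaptors, or in introns, are out of scope.
* The simulator's benchmark (and hence the acceptance numbers) reflects
  its stated world above, not any particular real dataset.
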