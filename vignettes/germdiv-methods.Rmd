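---
title: "Methods: dominant-marker diversity, multi-layer clustering, and tanglegram comparison"
author: "germdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker diversity, multi-layer clustering, and tanglegram comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

# The setting

A germplasm collection — cultivars, accessions, wild relatives — is
characterized on three layers: dominant PCR fingerprints (SRAP, SCoT,
ISSR, RAPD), mixed morphological traits, and CIELab color measurements
per organ region. Each layer yields a dissimilarity matrix and a
dendrogram; the scientific questions are (i) how informative each primer
is, (ii) how diverse each genotype's profile is, (iii) whether the
dendrograms faithfully represent their distance matrices, and (iv) how
strongly the classifications from different layers agree.

This vignette records the models, the conventions and the genuinely open
design choices, in that order. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# Dominant-marker statistics

Dominant bands are scored present/absent; a present band cannot separate
heterozygous from dominant-homozygous genotypes, so all statistics work
on the band-presence frequency $p$ — never on inferred allele dosages.
Missing calls are excluded from the denominator band by band; for
discriminating power (which needs complete multi-band patterns) genotypes
with any missing call among a primer's bands are dropped and $N$
adjusted.

Per band: $H = 1 - p^2 - (1-p)^2$, $\mathrm{PIC} = 1 - (p^2 + q^2) -
2p^2q^2$ (the two-state reduction of the general PIC double sum, which is
the only form defined for biallelic dominant data), and $I_b = 1 -
2|0.5 - p|$. These satisfy $0 \le \mathrm{PIC} \le H \le 0.5$ with
equality of PIC and H exactly at monomorphic bands, and maxima 0.375 and
0.5 at $p = 0.5$ — asserted as tests.

Per primer with $n$ bands, $PB$ of them polymorphic:
$\%P = 100 \cdot PB/n$, $E = PB \cdot (PB/n)$,
$\mathrm{MI} = \overline{\mathrm{PIC}} \times PB$,
$\mathrm{RP} = \sum I_b$, and Tessier's
$DP = 1 - \sum_i p_i (N p_i - 1)/(N - 1)$ over the distinct banding
patterns — equal to the probability that two genotypes drawn without
replacement display different patterns, which is how the tests verify it
(brute-force pair counting on small instances).

Conventions that the literature leaves open, each switchable:

* **Polymorphism criterion.** A band is polymorphic when both states are
  observed among non-missing calls (strict criterion, default). The
  common 95% rule (major state frequency ≤ 0.95) is available via
  `criterion = 0.95`; at typical panel sizes (~32 genotypes) the two
  differ only for bands carried by a single genotype in panels of 21+.
* **Effective multiplex ratio.** The classical definitions disagree in
  print. The default $E = PB\,(PB/n)$ weights the polymorphic band count
  by the polymorphic fraction; `emr = "fraction"` gives the bare
  fraction $PB/n$ for comparability with sources that define it so.
* **MI averaging.** Mean PIC is taken over all $n$ scored bands
  (default) or over polymorphic bands only (`micOver = "polymorphic"`).
* **Two percent-polymorphic summaries.** Panel summaries report both the
  pooled ratio $100\sum PB/\sum n$ and the unweighted mean of per-primer
  percentages; they differ whenever primers carry unequal band counts,
  and published tables mix the two, so both are emitted with distinct
  names.

GC content of primer sequences is reported to one decimal with **half-up
rounding**, the convention under which every printed value of the
published primer tables shipped in `inst/extdata/` is reproduced exactly
(24/24 in the golden test).

# Diversity indices

Shannon–Wiener $H' = -\sum p_i \ln p_i$ (natural log, the vegan
default), Gini–Simpson $\lambda = 1 - \sum p_i^2$, Pielou
$J = H'/\ln S$ over each genotype's nonnegative profile. For band
matrices the profile is the 0/1 call row — hence $H' = \ln k$ and
$J = 1$ for a genotype with $k$ bands, so on binary data the indices
mostly measure band counts. For trait and color layers, variables are
ordinal-coded and min–max scaled to $[0, 1]$ to obtain nonnegative
profiles. This profile construction is a package choice: sources rarely
state theirs, which is exactly why per-dataset index values are not
comparable across studies and are validated here only through their
analytic laws (uniform-profile maxima, scaling invariance).

# Distances

* **Binary** (simple-matching, Jaccard, binary-Euclidean) with pairwise
  deletion of missing calls; a pair with no compared band is an error,
  never a silent zero. Jaccard between two all-absent compared profiles
  is defined as 0 (identical profiles).
* **Gower** for mixed tables: mean over comparable features of
  $|x-y|/\mathrm{range}$ (quantitative) or 0/1 mismatch (qualitative),
  missing features excluded from numerator and denominator. Matches
  `cluster::daisy` on complete mixed data (tested).
* **Euclidean** with optional z-scoring by the *population* SD (divisor
  $N$) — chosen over the sample SD to make results bit-reproducible and
  stated here because the two differ by a factor $\sqrt{(N-1)/N}$ that
  cancels in clustering but not in raw distances. Missing data is a hard
  error: silent imputation would corrupt dendrograms downstream.
* **Pearson** profile similarity with $1-r \in [0,2]$ as distance;
  constant profiles are an error naming the offending unit.
* Qualitative variables entering Euclidean distance or PCA are
  ordinal-coded by their declared level order. Gower is the principled
  default for mixed tables; the ordinal+Euclidean route exists because
  practitioners use it, and the level order is an explicit, recorded
  codebook rather than an accident of factor construction.

# UPGMA, cophenetic validation, cutting

UPGMA merges the pair with minimal average-linkage distance at a height
equal to that distance; the distance from a merged cluster to any other
is the size-weighted average, so cluster distances always equal the mean
over leaf pairs. Heights are provably nondecreasing. Two deterministic
conventions:

* **Tie-break:** among minimal pairs, the lexicographically smallest
  pair of cluster representatives (a cluster is represented by its
  smallest leaf label) wins, and the smaller representative becomes the
  left child. Determinism is required for golden tests and for
  reproducible leaf orders; the correctness tests compare against a
  brute-force reference that recomputes every cluster-pair mean from the
  raw matrix at each step (1000 random matrices, $n \le 8$, including
  integer-valued matrices where ties are common).
* **Height scale:** merge heights are the raw merge distances (the
  `hclust` convention, not halved), so cophenetic values live on the
  input scale. The cophenetic correlation is the Pearson correlation of
  the $n(n-1)/2$ lower-triangle entries; it equals 1 exactly on
  ultrametric inputs (tested), and its value is unchanged by working on
  similarity rather than dissimilarity scale up to sign.

`cutTree` removes the $k-1$ highest merges and numbers clusters by first
appearance in the displayed leaf order, making partitions invariant (up
to relabeling) under input permutations.

# Tanglegrams

Entanglement is the normalized $L$-norm of leaf-rank differences between
the two displayed orders; 0 means perfectly aligned, 1 is the full
reversal that realizes the worst case. $L = 1.5$ by default — the
convention of the dendrogram-comparison tools in common use — exposed as
an argument. The package adopts the orientation *0 = good alignment*
throughout; descriptions in the literature occasionally label the range
the other way around while still reporting low values as good
alignments, so the orientation is fixed here once and logged by
`runPipeline()`.

Untangling searches rotation space only (rotations change displayed
order, never the tree): `step1side` sweeps the movable tree's internal
nodes root-to-leaf, accepting a flip only on strict decrease and
repeating until a full sweep changes nothing — which guarantees
termination; `step2side` alternates sides to joint convergence, with
optional seeded restarts; `random` keeps the best of seeded random
rotation states, the initial state included, so no method ever increases
entanglement (tested, along with idempotence at convergence). On trees
with ≤ 6 leaves, 10-restart `step2side` attains the global minimum found
by exhaustive search over all $2^{n-1} \times 2^{n-1}$ rotation
assignments of both trees (tested).

`matchedLeaves` cuts both trees at $k$, matches the partitions'
clusters by maximal overlap (exact assignment over permutations for
$k \le 7$, greedy beyond), and reports leaves whose matched cluster
agrees — the colored-line set of a tanglegram figure.

# PCA

Eigen-decomposition of the correlation matrix (covariance optional).
Eigenvalues are clamped at zero against floating-point noise; explained
percentages sum to 100 by trace conservation (tested); the sign of each
loading column is fixed by making its largest-magnitude entry positive.
Component selection: Kaiser (eigenvalue > 1, floor of one component with
a warning) or smallest count reaching a cumulative-percent threshold.

# The synthetic panel generator

`simulatePanel()` is first-class, tested code — it defines the study
conditions under which the pipeline's guarantees are demonstrated. The
defaults mirror a realistic ornamental-germplasm study: 32 genotypes in
K = 4 latent groups; a 26-primer SRAP-like layer (349 bands) plus a
12-primer SCoT-like layer (204 bands); 19 quantitative and 17
qualitative traits; CIELab triplets for six organ regions.

The marker model operates directly on band-presence frequencies — the
phenotypic level at which dominant markers are scored — not on diploid
allele dosage. Each band draws a baseline frequency from Beta(2, 2)
clamped to [0.02, 0.98]; a random half of the bands
(`shiftFraction = 0.5`) carries group structure, each group shifted by
$\pm\delta/2$ with equal probability, so two groups pulled in opposite
directions differ by $\delta$ in frequency. The signed form is a
deliberate choice: a one-directional $+\delta$ shift interacts with the
clamp so that expected between-group simple-matching distance can
*decrease* with $\delta$ (both-shifted bands saturate near fixation),
whereas signed shifts leave within-group distances untouched and raise
the between-group mismatch probability by $\delta^2/2$ on
opposite-shifted bands — giving the monotonicity that a separation
parameter must have (verified by Monte-Carlo trend over
$\delta \in \{0, 0.3, 0.6\}$). Default $\delta = 0.6$: strong but not
trivial structure, under which a 4-cluster UPGMA cut recovers the truth
with mean adjusted Rand index ≥ 0.9 over 20 seeds (tested and recomputed
by the acceptance script).

Quantitative traits are Normal with group means at $\Delta = 3$ noise-SD
units drawn per trait; qualitative traits give the group-favored level
probability 0.7; color channels are Normal per organ and group (L* means
in [20, 85], a*/b* in [−30, 40], SD 4) with L* clipped to [0, 100].
Because all three layers carry the same group labels, trees from
different layers of one panel are genuinely coupled — and the tests show
that coupled layers reach lower mean post-untangling entanglement than
trees from independently simulated panels (20 seeds).

What the generator does **not** emulate: linkage between bands,
coalescent or pedigree structure, trait–trait correlation beyond the
group signal, realistic color gamuts, genotyping error other than
missingness. Passing tests therefore demonstrate correctness of the
statistics and algorithms under a clean group-structured null, not
robustness to every artifact of real fingerprint data.

Determinism: every simulation routine seeds R's Mersenne–Twister via a
single `seed`, restores the caller's RNG state afterwards, and derives
per-layer sub-seeds from the master seed, so identical configurations
give identical panels on every platform.

# Degenerate inputs and numerical guards

* Band matrices: non-binary cells are rejected naming the genotype and
  band; all-missing bands are errors; at least two genotypes required.
* Achromatic color points ($a^* = b^* = 0$): chroma 0, hue undefined —
  returned as missing (strict mode errors), and hue columns with missing
  values are excluded from color distances.
* Constant features: dropped with a warning under standardization
  (Euclidean, PCA); constant profiles are errors for Pearson.
* Pairs with nothing to compare (all-missing overlap) are errors, never
  imputed.
* Heights, symmetry and zero diagonals are validated with 1e-12
  tolerances; ultrametricity of cophenetic matrices is tested
  exhaustively on small trees.

# Validation scale

The test suite runs the full oracle sweeps at the sizes stated above
(1000 random UPGMA instances at $n \le 8$; exhaustive untangling oracles
at $n \le 6$; 100 DP brute-force instances; 20-seed Monte-Carlo for
cluster recovery and coupling) in well under two minutes on one CPU —
sizes chosen so the whole suite is cheap enough to run on every change.
`scripts/acceptance.R` repeats the headline computations from scratch
against the installed package and writes them as JSON.

# Known limitations

* UPGMA only (the defining method for this analysis family); other
  linkages are out of scope by design.
* Untangling is a local search; optimality is only guaranteed where the
  exhaustive oracle can check it (small trees), which is why restarts
  are exposed.
* PIC/H/DP assume dominant biallelic scoring; codominant multi-allelic
  markers need different estimators and are not supported.
* Diversity-index values depend on the profile construction (above) and
  are not comparable across studies that constructed profiles
  differently.
* Primer melting temperatures are not computed: published tables rarely
  state their thermodynamic model, so any recomputation would be
  incomparable.
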