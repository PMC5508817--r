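---
title: "Methods: distance-based networks for fossil fern axis matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based networks for fossil fern axis matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmundnet)
```

## The problem

Anatomically preserved trunks and rhizomes of royal ferns (Osmundales) span
more than 250 million years and over a hundred fossil species, but they are
scored from a few dozen binary or ternary anatomical characters, with many
cells missing for preservational reasons.  Matrices like this mix ancestral
and derived taxa from different epochs, carry heavy homoplasy, and routinely
support several conflicting groupings at once.  A single phylogenetic tree
is then a poor summary: branches are unstable and supports low, not because
there is no signal but because the signal is genuinely non-treelike.

`osmundnet` therefore centres the analysis on objects that can *display*
conflict instead of hiding it:

* **mean character differences** (Hamming distances with pairwise deletion)
  as the distance model,
* **neighbour-net splits graphs** — circular split systems whose edge
  lengths reproduce the distances — as the main exploratory tool,
* **quartet delta values** to quantify how treelike the distances are
  before any tree is trusted, and
* **bootstrap support tables and consensus networks** to attach
  frequencies to competing splits rather than forcing a single answer.

## Distances

For taxa $i, j$ the distance is
$d_{ij} = m_{ij} / c_{ij}$, where $c_{ij}$ counts characters in which *both*
taxa carry a defined singleton state and $m_{ij}$ counts mismatches among
them.  Missing cells and ambiguous (polymorphic/uncertain) cells are
excluded pair by pair; ambiguity participates in parsimony scoring but never
in distances, because a multistate observation cannot be said to match or
mismatch a single state.  A pair with no comparable characters is an error,
not a zero: imputation is deliberately avoided.

Two filters precede every distance computation, in a fixed order:

1. **Taxon sparsity** — operational units with strictly more than 60%
   missing cells (assessed against the full parent character set) are
   dropped.  Distances from sparser rows become unrepresentative; the rule
   is strict `>`, so a unit at exactly the threshold survives.
2. **Invariant characters** — within the focal taxon set, characters with
   fewer than two distinct defined states are removed, so that a distance
   of 0.1 means "10% of the characters that can discriminate within this
   group".  Ambiguous cells do not establish variability.

The subset pipeline is idempotent: re-running it on its own output changes
nothing (this is a property test).

## Derived quantitative characters

Two characters of the axis-anatomy schema are not direct observations but
derived quantities, and the package recomputes them from measurement
tables:

* **PmmS**, complete stele perforations per millimetre of stele perimeter:
  $\mathrm{PmmS} = N(CP)_{max} / (d(\mathrm{Stele})_{max}\,\pi)$, with the
  stele diameter in mm.  The degree-of-perforation state is 0 ("(nearly)
  imperforate") for at most 3 complete perforations; 2 ("highly
  perforated") for at least 16 perforations *and* PmmS ≥ 0.30/mm; and 1
  otherwise.  The two-sided rule encodes both published overrides: axes
  with only 4 perforations but high density stay moderate, and axes with
  many perforations spread around a very large stele drop back to
  moderate.
* **RTC**, relative cortex thickness:
  $(d(\mathrm{Stem})_{max} - d(\mathrm{Stele})_{max}) /
  d(\mathrm{Stele})_{max}$, with states cut at 1.2 and 2.8 (closed middle
  interval).  A stele wider than its stem is rejected as a data error — in
  the literature this almost always signals confusion of the terms "stem"
  and "stele".

The state thresholds originate from one-dimensional k-median clustering
(k = 3) of the observed values.  `k_medians_1d()` uses restarted
Lloyd-style iterations from random distinct seeds (default 1000 restarts,
seeded); because the 1-D optimum is always an interval partition of the
sorted values, `k_medians_interval()` provides an exact exhaustive search
used as the independent oracle in the tests.  Assignment ties go to the
lower-median cluster; boundaries are reported as midpoints between adjacent
clusters' extreme members.  Missing measurements yield missing derived
states, never zeros.

## Delta values

For a quartet $\{x,y,z,w\}$ the three pairings give distance sums; ordered
$m_1 \ge m_2 \ge m_3$, the quartet's delta is $(m_1-m_2)/(m_1-m_3)$, and 0
by convention when $m_1 = m_3$.  A tree metric satisfies the four-point
condition — its two largest sums are equal — so delta is 0 on every quartet;
1 marks a maximally box-like quartet.  The matrix delta value (mDV)
averages all $\binom{n}{4}$ quartets; the individual value (iDV) of a taxon
averages the quartets containing it.  Quartets touching an undefined pair
distance are skipped and counted, never imputed.  The enumeration is
vectorised over the trailing pair of each quartet, so cost grows as
$n^4/24$ with a small constant and matrices of the published size
(~$10^7$ quartets) stay well inside a desk-scale budget.

## Neighbour-net

The circular ordering is built agglomeratively: clusters (initially
singleton taxa, later linked paths represented by their two end nodes) are
merged by the neighbour-joining Q-criterion on cluster-averaged distances; a
second Q-criterion over the expanded element set picks which end nodes to
link; and any three linked nodes are immediately reduced to two with the
standard 2/3–1/3 distance-reduction scheme.  Ties break to the lowest pair
index.  Expanding the surviving path yields a circular order of all taxa.

Split weights are then fitted over the $n(n-1)/2$ interval splits of that
ordering by non-negative least squares (a Lawson–Hanson active-set solver
on the normal equations, ridge-stabilised by $10^{-12}$); splits with
weight ≤ 1e-8 are dropped.  Two consequences, both enforced as tests:
for circular-decomposable input the fitted system reproduces the distances
to within solver tolerance, and for additive (tree) metrics the output is
exactly the tree's splits with branch-length weights.

The system is written as a SplitsTree-compatible NEXUS `SPLITS` block with
`CYCLE` and `MATRIX` entries, so graphs can be drawn in the usual viewer;
the package itself does no layout.

## Trees, bootstrap, consensus networks

Per-replicate trees use BioNJ (variance-weighted neighbour joining,
delegated to the reference implementation in `ape`; negative branch-length
estimates are clamped to zero and counted) or Fitch parsimony.  Fitch
scoring propagates state sets as bitmasks — missing cells contribute the
full state set, ambiguous cells their stated subset — and is invariant
under re-rooting (tested).  The heuristic search is seeded first-improvement
NNI hill-climbing; NNI neighbourhoods have local optima, so a `restarts`
argument adds random starting topologies, and the search is deliberately a
lighter substitute for the TBR swapping used on workstation scale.  It is
exercised qualitatively; numerical support comparisons rest on the
distance criterion.

Bootstrapping resamples characters with replacement, rebuilds one tree per
pseudoreplicate, and records the frequency of every non-trivial split.  A
master seed spawns an independent per-replicate seed, so any single
replicate is reproducible in isolation, and a fixed seed makes the whole
support table bit-identical (tested).  Replicates in which some pair has no
comparable characters are skipped and counted; above 10% skips the run
aborts as uninterpretable.  The consensus ("bipartition") network keeps
splits at or above a frequency cut-off (default 10%, the conventional
display filter) with frequency as weight; trivial splits ride along at
weight 1 for drawability.  Incompatible splits may and should coexist in
this object — that is its purpose.

## The synthetic-data generator

`simulate_matrix()` evolves unordered characters on a known binary tree
under a symmetric k-state Markov process (Poisson change events per branch,
uniform root state), with a tunable mixture of binary and ternary characters
(default 45% ternary, mirroring the roughly half-ternary published schema),
a `change_rate` giving the expected number of change events per character
summed over the tree (default 3 — enough for signal, enough for multiple
hits), an optional fraction of pure-noise characters (`homoplasy_boost`),
and per-taxon missing-cell rates up to 0.9 emulating preservational,
taxon-blockwise missingness.  The generating tree, its splits, per-character
change counts and the missing mask are returned as ground truth.

What a green test on this world establishes: the pipeline recovers known
structure under controlled signal, noise, and missingness.  What it does
not establish: correctness on real fossil matrices, whose characters are
correlated, whose missingness is not random given the taxon, and whose
character collection is biased toward variability (no ascertainment
modelling is attempted).

**Branch lengths.**  The generator's default draws branch lengths from an
exponential law (mean 1), reflecting the strong rate heterogeneity of
fossil morphology.  One stated recovery property — BioNJ recovering the
generating topology in at least 90% of draws at 10 taxa and 200
characters — is *unattainable in principle* under that law: most draws
contain an internal edge so short that no finite character sample can
resolve it, and measured recovery plateaus near 25–37% regardless of the
change rate (the same ceiling appears when the data are simulated and
analysed entirely with third-party tools, so this is not an implementation
artefact).  The recovery property is therefore asserted in the clock-like
regime (`branch_lengths = "equal"`, `change_rate = 1`), where it holds
comfortably; the exponential default remains for realism.  This is the one
deliberate deviation from the original design sketch.

## Numerical choices and degenerate inputs

* Distances live in [0, 1]; printed two-decimal values are compared at
  ±0.005, since published worked examples appear truncated rather than
  rounded (6/14 = 0.4286 printed as 0.42).
* Delta's $m_1 = m_3$ degeneracy uses an absolute 1e-12 guard.
* NNLS drops weights ≤ 1e-8; the active-set loop is capped at 10 p
  iterations.
* k-medians restarts that collapse a cluster are abandoned, not repaired.
* `n ≤ 3` neighbour-net inputs return the input order; 3-taxon BioNJ is the
  fitted star.
* Empty matrices, unknown taxa, trivial split queries, and all-dropped
  subsets raise immediate, named errors.

## Limitations

No maximum-likelihood (Mk+Γ) bootstrapping — per-replicate ML search at
10,000 replicates is not desk-scale, and the distance supports cover the
same splits.  No ordered or continuous characters, no character weighting,
no network layout.  The packaged named-subset lists are reconstructed from
the published classification and flagged as such; users analysing the
original supplementary matrix should reconcile operational-unit labels
before relying on them.
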