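---
title: "Methods: kinship-based contemporary gene flow and migration networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship-based contemporary gene flow and migration networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinflow)
```

`kinflow` analyses temporally replicated microsatellite samples of a
partially migrating metapopulation: the same sites sampled in several
consecutive seasons, each individual typed at a panel of codominant SSR
loci. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices, and what the simulator can
and cannot validate.

## Data model

A dataset is a long genotype table (individual × locus, two integer
allele lengths, both `NA` when missing — half-calls are rejected) plus a
population table with site coordinates, sampling dates and an integer
time code. Alleles are raw fragment lengths; no repeat-unit binning is
applied, because cross-plate bin reconciliation cannot be reconstructed
after the fact and length-coded calls are what scoring software exports.
GenAlEx codominant CSV (missing = `0`) and STRUCTURE two-row (missing =
`-9`) files round-trip exactly.

## Diversity statistics

Per locus and population: `Na` (alleles observed), effective allele
number `Ne = 1/Σp²`, Shannon `I = −Σ p ln p`, observed heterozygosity
`Ho`, and expected heterozygosity `He = 1 − Σp²`. Rows report unweighted
means over loci; loci with no data in a population are dropped from that
population's mean with a message. Two conventions deserve note:

* `He` is the plug-in estimator; the small-sample `2N/(2N−1)` correction
  is available via `unbiased = TRUE` but off by default, matching the
  convention of the standard spreadsheet tools whose output these tables
  mirror.
* Diversity tables in this literature sometimes label `1/Σp²` as
  "effective population size"; it is the effective *allele* number
  (values of order 2–5 per locus), and that is what `Ne` here means.

### Rarefaction

Unequal sample sizes make raw allele counts incomparable, so group-level
richness uses rarefaction on gene copies. For a locus with `N` typed
copies of which `N_a` carry allele `a`, the probability the allele is
absent from a uniform subsample of `g` copies is the hypergeometric tail
`Q(a, g) = C(N − N_a, g)/C(N, g)` and the expected number of distinct
alleles is `Σ_a (1 − Q(a, g))`. The private-allele estimator for a focal
group multiplies in `Π_k Q_k(a, g)` over every other group, i.e. the
probability that equal-sized subsamples of all other groups miss the
allele. Both are averaged over loci; loci with fewer than `g` copies in
any participating group are unavailable at that `g` and are dropped from
the average (the curve is truncated, never extrapolated).

Binomial coefficients are evaluated in log space (`lchoose`), so group
sizes of hundreds of copies pose no overflow risk; the unit tests verify
exact (1e-12) agreement with exhaustive subset enumeration wherever a
locus has at most 8 copies. The distinct-allele curve is non-decreasing
in `g` and reaches the observed count at `g = N`. The private-allele
curve is *not* monotone in general: as `g` grows, the focal subsample
gains alleles but the other groups' subsamples also get better at
containing them, and the second effect can dominate (two identical
`{A:3, B:3}` groups have expected private richness 0.32 at `g = 2` and 0
at `g = 6`). Only full-sample privacy (`g = N`) equals the naive
"allele seen in no other group" count.

The per-population `Ar` column is reported at a user-chosen `g`
(`ar_g`): published tables of this kind rarely state the rarefaction
depth behind their `Ar` column, so no default is imposed.

## Distances, ordination, isolation by distance

Nei's (1972) standard distance uses `J_X = Σp²`, `J_Y = Σq²`,
`J_XY = Σpq` averaged arithmetically across loci *before* forming
`I = J_XY/√(J_X J_Y)` and `D = −ln I` (the behaviour of the standard
spreadsheet implementation, not the per-locus-D average). Pairs sharing
no alleles at any locus get `D = ∞`, which is flagged and excluded
pairwise from downstream analyses rather than silently capped; PCoA
refuses infinite input outright with advice, because a capped value would
silently distort the whole embedding.

PCoA is classical metric scaling: Gower double-centering of `−d²/2`,
eigendecomposition, coordinates scaled by `√λ`. Negative eigenvalues
(non-Euclidean distance matrices) are reported but excluded from the
percent-variance denominator.

Geographic distances are haversine great circles on a sphere of mean
radius 6371.0088 km. An ellipsoidal geodesic differs by under 0.5%,
irrelevant at the hundreds-to-thousands-of-km scale of windborne
migration.

Isolation by distance is tested with a Mantel permutation test: Pearson
`r` over the `n(n−1)/2` population pairs, with rows and columns of one
matrix permuted jointly (`n_perm` default 9999, seed required) and a
two-sided `p = (1 + #{|r*| ≥ |r|})/(n_perm + 1)`. A permutation null is
used because distance-matrix entries are not independent, so an ordinary
regression p-value would be anticonservative.

## Parentage likelihoods

The kinship stage asks, for every individual in a time slice treated as
an offspring, which other individual is most plausibly one of its
parents. The single-locus likelihood uses the standard parent–offspring
transition probability with one unknown parent integrated over the gene
pool, wrapped in a genotyping-error model: each *observed* allele is,
with probability `e`, a replacement drawn from the locus's pooled allele
frequencies (class-II error; allelic dropout is not modelled). Writing
`f(x|t) = (1−e)·1[x = t] + e·p_x` and `M(x|G)` for the probability that
the candidate transmits an allele observed as `x` (integrating a
Hardy–Weinberg posterior over the candidate's true genotype given its
observed one), the likelihood ratio against "unrelated member of the gene
pool" is

* heterozygous offspring `{x, y}`: `LR = (M(x)/p_x + M(y)/p_y) / 2`
* homozygous offspring `{x, x}`: `LR = M(x)/p_x`

and the multi-locus LOD is the sum of `log10 LR` over loci typed in both
individuals (at least `min_shared_loci = 10` of the panel's 15 by
default). At `e = 0` a single Mendelian-incompatible locus drives the
LOD to `−∞`; with `e > 0` it is finite everywhere, which is why the
error model matters for microsatellites. Background frequencies are
pooled over the whole time slice, not per population — per-population
frequencies would bias the ratio against exactly the cross-population
pairs the analysis is looking for.

Design choices that were genuinely open:

* **One parent per offspring, sex ignored.** Field samples of moths have
  no recorded sex, so paternity and maternity cannot be distinguished;
  the retained quantity is the parent–offspring *link*, which is what
  the migration network consumes. Polygamy is implicit (one individual
  may be the best parent of many offspring).
* **Symmetric candidate convention.** Every individual is both a
  potential offspring and a potential parent; generations overlap within
  a field sample and cannot be separated by age. A consequence is that a
  true parent–offspring pair can be retained in either or both
  directions.
* **Inbreeding is not modelled** (no inbreeding coefficient in the HWE
  prior); with the error model's posterior over true genotypes, this
  only matters at extreme consanguinity.

### Threshold calibration

A pair's LOD is accepted when it reaches a Monte-Carlo threshold.
`lod_threshold()` simulates unrelated genotype pairs from the pooled
frequencies (through the error model) and takes an upper quantile
(default 0.999) of the null LOD distribution. Crucially, an assignment
scan does not test one pair: it takes the *best* of `n − 1` candidates,
and the maximum of hundreds of null LODs routinely exceeds a single-pair
quantile. `assign_parentage()` therefore calibrates against the maximum
LOD among as many simulated unrelated candidates as the scan evaluates
(`n_candidates = n − 1`), the convention of simulation-calibrated
parentage software, making `1 − quantile` the per-offspring
false-assignment probability independent of sample size. The single-pair
null remains available (`n_candidates = 1`) and is the right object for
per-pair error-rate statements. Ties in the best-candidate LOD are broken
toward the lexicographically smaller id, with a message, so reruns are
identical.

The stricter family-wise threshold trades a little recovery for clean
migration matrices: a true parent whose LOD lands below the max-null
quantile is dropped. With the default panel (15 loci, ~10 alleles each)
recovery of true parents at complete parent sampling sits around 90%,
and essentially every retained pair is a genuine link — the regime the
downstream network construction wants, since a single false pair creates
a spurious directed edge.

### Error-rate robustness

`error_rate_robustness()` re-runs the assignment under each rate of a
grid (default 1e-4, 1e-3, 1e-2, 5e-2; primary rate 1e-4) and reports the
pairwise Jaccard overlap of retained pair sets plus the correlation of
per-population-pair counts. Markers are deemed informative when every
Jaccard reaches 0.8. Borderline pairs near the threshold churn as the
threshold recalibrates per rate, so Jaccard is the conservative metric;
the count correlations, which drive the migration matrices, are typically
above 0.99 on clean data.

## Migration rates and networks

Cross-population parentage links are counted into a destination × origin
matrix (`n[i, j]` = offspring sampled in `i` with assigned parent in
`j`). Row-normalising gives the multinomial MLE of contemporary migration
rates with Wilson 95% score intervals per cell (cell-versus-rest
binomial). Two scale conventions matter when validating against a
simulator:

* Each offspring has two parents, and the resident parent is as likely
  to be the retained best candidate as the migrant one. Single-parent
  assignment therefore estimates the **per-parent-draw** migration rate,
  `(M[i,j] + 1[i = j])/2` in the simulator's terms — roughly half the
  migrant-*offspring* fraction. `realized_migration(per_parent = TRUE)`
  produces the matched ground truth, and the package's recovery checks
  compare on that scale.
* Rates condition on assignment: rows with no assigned offspring are
  flagged undefined rather than zero.

The directed network has an edge origin→destination wherever an
off-diagonal count is ≥ 1 (edges are presence/absence, not weights — a
deliberate choice given small per-pair counts); node degree is in + out
over directed edges. The clustering network is the undirected projection
weighted by shortest-path edge betweenness (computed on the unweighted
projection first), clustered by fast-greedy modularity maximisation.
The partition returned is the cut of the merge hierarchy with maximal
recomputed Q — the hierarchy's own argmax is not trusted on small graphs
— with ties resolved toward fewer clusters. Components are clustered
independently; isolated nodes are singleton clusters; an edgeless graph
has Q defined as 0. Sources and sinks are read off degree asymmetry
(`in > out` = sink), and key nodes are per-cluster and global degree
maxima plus bridge nodes incident to inter-cluster edges.

Migration distances are haversine lengths of the directed edges, per
slice and pooled, summarised with mean, quartiles, maximum and a
Student-t 95% CI for the mean (undefined for a single edge; a bootstrap
CI was considered and rejected as spurious precision at these edge
counts).

## The simulator

`simulate_metapopulation()` is a forward-time, non-overlapping-
generations model whose point is ground truth, not demographic realism.
Defaults mirror the study design the package targets: 12 demes on an
800 km grid, 15 loci with 10 alleles drawn from a flat Dirichlet, four
consecutive sampled episodes of 32 offspring per deme plus a fraction
(default 0.25) of the parental cohort, migration via the second parent
(resident probability 0.85, distance-decay kernel with 1000 km scale —
the distance scale reported for windborne moth migration), genotyping
error 1e-3 and missingness 0.02 on emitted genotypes only. Every
offspring records both parents and the migrant parent's deme, so
recovery, false-assignment and rate-coverage properties are measurable
exactly.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about field data: mutation (off by default; slices span
few generations), null alleles and allelic dropout, family-correlated
sampling (field protocols space collections to avoid sibling clumps; the
simulator samples uniformly), sex-biased dispersal, overlapping
generations within a deme, and selection. Genotyping error in the field
may also be locus-specific rather than uniform.

## Numerical and reproducibility choices

* All binomial coefficients in rarefaction via `lchoose`; exact integer
  enumeration only in tests (≤ 8 copies).
* Every stochastic function takes an explicit seed and restores the
  global RNG state on exit; the pipeline fans a master seed out through
  a fixed counter scheme, so any stage can be reproduced in isolation
  and two runs with the same seed write byte-identical CSVs.
* Tie-breaks are deterministic everywhere (lexicographic candidate ids;
  fewer clusters at equal Q).
* Degenerate inputs fail loudly with the offending population, locus or
  node named: empty datasets, populations with zero typed loci,
  monomorphic-only frequency sets (threshold warning), infinite
  distances in PCoA/IBD, missing coordinates in distance summaries.

Validation problem sizes were chosen to make the statistical checks
sharp but quick: rarefaction oracles enumerate loci of ≤ 8 gene copies;
graph oracles cover random graphs of ≤ 8 nodes and clique families of
≤ 10; kinship calibration uses two demes of 150–200 adults with complete
parent sampling; migration-rate coverage uses 100 seeded replicates of a
two-deme system with a 0.3 migrant-parent fraction; the Mantel null uses
500 twelve-label replicates. The full suite and the acceptance script
each run in minutes on a single core.

## Known limitations

* Pairwise single-parent assignment cannot use sibship information; a
  full-likelihood joint sibship/parentage reconstruction would squeeze
  more out of the same markers at much higher computational cost.
* Migration rates are conditional on assignment and uncorrected for
  unsampled parents; absolute rates are therefore best interpreted
  comparatively (between population pairs and seasons), which is also
  how the network stage consumes them.
* Betweenness-weighted modularity clustering inherits the quirk that
  bridge-heavy edges carry large weights; it is kept because it is the
  construction used in this analysis tradition, with the unweighted
  variant one flag away (`weights = "none"`).
* With very small panels (few, low-diversity loci) the LOD null and the
  true-parent distribution overlap substantially; `lod_threshold()`'s
  null draws make this visible, and the honest response is more loci,
  not a lower quantile.
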