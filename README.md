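# kinflow

Temporal population-genetics toolkit for highly dispersive insect pests
(and other partially migrating metapopulations) typed at codominant
microsatellite (SSR) loci. `kinflow` is aimed at molecular ecologists who
sample the *same* sites repeatedly over time and want to know not just how
genetic variation is structured, but **where this season's individuals
came from**: which populations are sources, which are sinks, and how far
migrants actually moved.

The pipeline follows the logic of contemporary (kinship-based) gene-flow
analysis rather than historical `Nm`/`F_ST`-style inference:

1. **Diversity and structure per sampling time.** Per-population `Na`,
   `Ne = 1/Σp²` (effective allele number), Shannon `I = −Σp ln p`, `Ho`,
   `He = 1 − Σp²`, plus rarefaction of distinct and private allelic
   richness for populations pooled by sampling time: the expected number
   of alleles in a standardized draw of `g` gene copies,
   `E[A] = Σ_a (1 − C(N−N_a, g)/C(N, g))`, and its private-allele
   analogue multiplying in the probability that the allele is absent from
   equal-sized draws of every other group.
2. **Distance and ordination.** Nei's (1972) standard distance
   `D = −ln( J_XY / √(J_X J_Y) )` with the `J` terms averaged across loci,
   principal coordinates (Gower double-centering), haversine geographic
   distances, and a two-sided Mantel permutation test of isolation by
   distance.
3. **Parentage under a genotyping-error model.** For each offspring the
   best candidate single parent by multi-locus LOD,
   `LOD = Σ_l log10 [ P(offspring | candidate parent, random mate) /
   P(offspring | unrelated) ]`, where each observed allele is, with
   probability `e`, a random allele from the locus's frequency
   distribution. Acceptance thresholds are Monte-Carlo calibrated against
   the *maximum* LOD among as many simulated unrelated candidates as the
   scan evaluates, so the per-offspring false-assignment rate equals
   `1 − quantile` regardless of sample size. Robustness is checked across
   an error-rate grid (1e-4, 1e-3, 1e-2, 5e-2).
4. **Migration networks.** Cross-population parentage counts become a
   directed origin→destination migration matrix (row-normalised
   multinomial rates with Wilson intervals), a directed unweighted
   gene-flow network with degree centrality, an undirected
   betweenness-weighted network clustered by fast-greedy modularity
   maximisation, source/sink labels from in/out-degree asymmetry,
   key-node reports, and geodesic migration-distance summaries.
5. **A forward-time simulator** with known pedigree and migration matrix,
   used to validate every stage end-to-end (migration acts through
   parentage: an offspring's second parent is drawn from deme `j` with
   probability `M[i, j]`).

File interchange covers GenAlEx codominant CSV and STRUCTURE two-row
formats; site metadata (coordinates, sampling dates, time codes) rides
along in a plain CSV.

## Worked example

Simulate a 6-deme metapopulation sampled in two seasons, then run the
kinship → network stages on the first time slice:

```r
library(kinflow)

cfg <- sim_config(n_demes = 6, deme_size = 150, sample_per_deme = 32,
                  parent_sampling_fraction = 0.5, n_time_slices = 2,
                  seed = 42)
sim <- simulate_metapopulation(cfg)
tabulate_by_time(sim$data)
#> # A tibble: 2 × 3
#>   time_code n_populations n_individuals
#>       <int>         <int>         <int>
#> 1         1             6           642
#> 2         2             6           642

sl    <- time_slice(sim$data, 1)
pairs <- assign_parentage(sl, error = 1e-4, seed = 7, n_sim = 2000)
head(pairs, 2)
#> # A tibble: 2 × 7
#>   offspring offspring_pop parent   parent_pop   lod n_loci_compared n_mismatch
#>   <chr>     <chr>         <chr>    <chr>      <dbl>           <int>      <int>
#> 1 G2_A_010  A1            G3_A_022 A1          8.27              15          0
#> 2 G2_A_012  A1            G3_A_037 A1          6.02              14          0

net <- build_network(migration_counts(pairs, sl), sl)
cluster_migration(net)
#> <migration_clustering> 2 cluster(s), Q = 0.126 (betweenness-weighted)
migration_distance_summary(net)
#> 12 migration edges, mean 946.2 km (95% CI 705.8-1186.5), max 1755.0 km
```

Each retained pair is one piece of contemporary gene-flow evidence: the
LOD column is the log10 likelihood ratio for parenthood versus an
unrelated individual, `n_mismatch` counts loci that would be Mendelian
exclusions under error-free typing, and cross-population pairs (offspring
population ≠ parent population) are the directed edges of the migration
network. Under the default distance-decay migration kernel (1000 km
e-folding scale on an 800-km site grid) the mean realized migration edge
sits near 1000 km.

`run_pipeline()` chains every stage per time slice and adds cross-slice
summaries (source/sink persistence, cluster counts per season); results
come back as one bundle and, optionally, a directory of CSVs that is
byte-reproducible under the master seed.

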