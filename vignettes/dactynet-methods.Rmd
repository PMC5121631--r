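---
title: "Methods: habitat structure in orchid mycorrhizal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat structure in orchid mycorrhizal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dactynet)
```

`dactynet` analyses the association between terrestrial orchids and their
root mycorrhizal fungi from an OTU read-count table, asking whether
community composition and the topology of the species–fungus network are
structured by habitat rather than by host ploidy. This vignette documents
the statistical machinery, the defaults and why they were chosen, the
synthetic data model used for validation, and the known limitations.

## Data model

Three tab-separated tables drive everything:

* an **OTU table** — samples (individual orchid roots) × fungal OTUs,
  non-negative integer read counts. Counts are the only stored currency;
  relative abundances and presence/absence are derived downstream, never
  stored, so there is a single canonical representation.
* **sample metadata** — species, population, habitat and ploidy per sample.
  Habitat (`mediterranean`, `peat_bog`, `wetland`, `coastal`,
  `alpine_boreal`) and ploidy (`2x`, `3x`, `4x`) are closed vocabularies:
  a typo fails loudly at read time rather than silently creating a new
  group in a permutation test.
* **taxonomy** — per OTU, the best-hit family or clade and its percent
  identity.

Readers reject duplicated identifiers, ragged rows and non-integer counts;
writers are byte-stable so that a write–read–write cycle reproduces files
exactly, which makes determinism testable at the file level.

## Filtering

Two column filters are applied, in either order (they commute):

1. **Rarity** (`remove_rare_otus`): OTUs whose *whole-dataset* total is
   below 3 reads — global singletons and doubletons — are removed. Such
   reads are dominated by sequencing artefacts and inflate diversity
   estimates.
2. **Mycorrhizal status** (`flag_mycorrhizal`, `subset_mycorrhizal`): an
   OTU is kept when its family/clade is on the orchid-mycorrhizal whitelist
   *and* its identity strictly exceeds 90%. The inequality is strict by
   design — a hit at exactly 90.0% is excluded — and the default whitelist
   (Tulasnellaceae, Ceratobasidiaceae, Sebacinales A and B, Thelephoraceae)
   covers the families that dominate orchid mycorrhizas in temperate
   Europe; both the threshold and the list are arguments.

Presence of an OTU in a species or population means ≥ 1 read after
filtering in at least one sample of that group. No per-sample minimum is
imposed: the rarity filter already operates at the dataset level, and any
additional cutoff would be an undocumented second threshold.

## Community composition

The analysis unit is the **species-level presence/absence profile** with
Jaccard dissimilarity, `d = 1 − |A∩B| / |A∪B|`. Read counts from amplicon
sequencing are compositional and heavily depth-dependent, and pooling
samples per species makes sampling effort per point comparable; Bray–Curtis
on summed counts (`d = 1 − 2Σ min(x_j, y_j)/(Σx + Σy)`) is available where
abundance information is wanted. The choice is recorded in every pipeline
summary for provenance.

**NMDS** minimises Kruskal stress-1 through `vegan::monoMDS` (global
model, weak tie treatment). The first start is the classical metric-MDS
configuration, remaining starts are uniform random; the best of
`n_restarts = 20` is returned with its convergence flag, and coordinates
are centred at the origin. Two points embed trivially at zero stress;
`k` may not exceed `n − 1`.

**Permutational MANOVA** is computed directly from the distance matrix:

* `SS_total = Σ_{i<j} d²_ij / n`, `SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`,
* `pseudo-F = (SS_between/(a−1)) / (SS_within/(n−a))` for `a` groups,
* `p = (1 + #{F_perm ≥ F_obs}) / (1 + B)` over `B` uniform label
  permutations.

Including the observed statistic in both numerator and denominator makes
the test exact under exchangeability and floors the p-value at `1/(B+1)`
(0.001 at the default 999 permutations). On Euclidean distances from
univariate data the statistic collapses to the classical one-way ANOVA F,
which the test suite verifies to 1e-10, and `vegan::adonis2` is used as an
independent cross-check. Ploidy is tested as diploid versus polyploid by
default (`ploidy_binary = TRUE`): with a single triploid lineage a
three-level factor would give one group of size one.

## Network modularity

The bipartite network links each orchid species to the OTUs observed in it.
Modules are sought over **joint partitions** of species and OTU nodes —
modules contain both — maximising

$$M = \sum_s \left[ \frac{l_s}{L} - \left(\frac{d_s}{2L}\right)^2 \right]$$

with `L` links in total, `l_s` links internal to module `s`, and `d_s` the
summed degrees of its nodes. `M = 0` exactly for the single-module
partition and `M ≤ 1 − 1/N_M` for any partition into `N_M` modules (the
index can be negative; a published description giving "0 to −1/N_M" as the
range is a typo for this standard bound, and the implementation asserts the
standard bound).

### Simulated annealing

Maximisation uses a Guimerà–Amaral-style annealer (C++):

* moves: single-node reassignment (with a 10% chance of proposing a fresh
  module), plus collective merges and random bipartitions of a module;
* acceptance: worse moves accepted with probability `exp(ΔM/T)`;
* schedule: `T₀` auto-scaled so ~97% of initially worsening single moves
  are accepted, geometric cooling (`cooling = 0.995`), `f·n²` single and
  `f·n` collective moves per temperature (`move_factor = f = 1`), stopping
  after `patience = 3` temperatures without improvement *once the chain is
  frozen* (single-move acceptance below 25% — without the freeze condition
  a slow schedule can stop while still hot);
* the best partition seen is greedily polished: best single-node moves and
  pairwise merges to a local optimum, accepting zero-gain merges so that
  ties resolve toward fewer modules (a complete bipartite graph returns one
  module, not an arbitrary zero-modularity split);
* `n_restarts = 5` independent runs, best M kept; all randomness flows from
  a private Mersenne Twister stream, so results are bit-reproducible for a
  given seed.

Module labels are canonical — numbered by decreasing size, ties broken by
the lexicographically smallest member — so equal partitions compare equal.
On networks small enough to enumerate every set partition, the annealer
attains the exhaustive maximum (verified on 50 random networks of up to 8
nodes in the test suite).

### Null model

Significance compares `M_obs` with modules detected on networks randomised
by **checkerboard trial swaps**: a uniformly chosen 2×2 submatrix is
swapped whenever it is `[[1,0],[0,1]]` or its mirror. This preserves *both*
degree sequences exactly — stricter than matching only the species degrees,
and standard for binary incidence data. Because the proposal distribution
is symmetric and the swap graph connects all matrices with the given
margins, the chain's stationary distribution is uniform over them (the
suite checks this against the full enumeration of a 4×4 fixture, 90
fillings, by chi-square at α = 0.01). Each null draw takes `10·L` trial
swaps from the observed network, and the nulls are re-optimised with the
*identical* annealing schedule and restart count as the observed network,
so optimisation bias cancels in the comparison;
`p = (1 + #{M_null ≥ M_obs}) / (1 + n_null)`.

## Indicator species

For a site group `g` (a habitat or a union of habitats):

* specificity `A = mean abundance over sites of g / (that mean + Σ of the
  per-habitat means outside g)` — scale-free per OTU;
* fidelity `B` = fraction of sites of `g` where the OTU occurs;
* `IndVal = √(A·B)`, maximised over all unions up to
  `max_order = #habitats − 1`, ties resolved to the smallest union and then
  lexicographically.

Significance permutes site labels and recomputes each OTU's
*best-combination* statistic, so the maximisation over unions is inside the
permutation loop and does not inflate significance. Sites are
**populations** (samples pooled, converted to within-site relative
abundance to guard against depth artefacts); both the site unit and the
abundance basis are arguments. An OTU absent everywhere has undefined `A`
and is reported `NA`, not 0. No multiple-testing correction is applied by
default, matching common practice of reporting raw indicator significance;
Benjamini–Hochberg adjustment is available via `adjust = "BH"`.

## Synthetic data model

`simulate_dataset()` emulates the sampling design the package targets:
14 orchid species allocated 4/2/4/2/2 across the five habitats, one to
three populations per species (38 in the paper-scale preset), three root
samples per population (114 samples), and ~115 mycorrhizal OTUs.

* **Association structure**: each OTU belongs to a habitat block (sizes
  proportional to species numbers per habitat) and links to a species of
  its habitat with `p_within = 0.5`, to others with `p_between = 0.02`;
  a small fraction (`generalist_fraction = 0.05`) are generalists linking
  to any species with probability 0.5. This yields the empirically observed
  pattern that most fungi occur in only one or two orchid species, with a
  few widespread generalists, and per-species OTU richness of roughly 7–27
  (the observed range in comparable surveys is 6–34).
* **Planted indicators**: one OTU per habitat is linked to *all* species of
  its habitat and none other, with a threefold abundance effect — ground
  truth for the indicator test.
* **Read counts**: per sample, linked OTUs receive negative-binomial counts
  (`size = 0.5`, strongly overdispersed, as typical for amplicon data) with
  means proportional to log-normal OTU effects (`sdlog = 1`), scaled to an
  expected depth of 830 reads per sample (log-normal depth variation,
  `sdlog = 0.3`); ~830 is the per-sample mean implied by ~94,500 reads over
  114 samples in the motivating survey.
* **Spike-ins**: 20 rare OTUs with whole-dataset totals of exactly 1 or 2
  (deterministic exercise of the rarity filter), 25 OTUs from genera of
  doubtful mycorrhizal status (Mycena, Armillaria, Inocybe, ...), and 2
  whitelisted-family OTUs with identity below 90% (exercising the strict
  cut).

Everything is drawn under a single seed and is byte-reproducible. The
generator does **not** simulate sequencing error, chimeras, phylogenetic
relatedness among OTUs, spatial autocorrelation among populations, or
year-to-year variation; passing recovery tests therefore demonstrates the
*statistical machinery*, not robustness to those real-data complications.
Note also that because every species belongs to exactly one habitat, any
species-linked OTU is genuinely habitat-associated at the site level; a
meaningful false-discovery check for the indicator test therefore uses a
background of ubiquitous generalists (site-exchangeable by construction),
which is how the suite tests it.

## Numerical and design choices

* All permutation p-values use the add-one convention, so `p ≥ 1/(B+1)`.
* Random number use is isolated: every stochastic function takes a `seed`
  and restores the caller's RNG state; the pipeline derives independent
  per-stage seeds from its master seed by a fixed affine rule (stage
  results are reproducible in isolation, verified in the tests).
* Degenerate inputs fail with named errors: all-zero samples in a
  dissimilarity, one-group permutational MANOVA, zero within-group sum of
  squares, missing taxonomy records, empty sample intersections.
* The test suite and the acceptance script use a reduced annealing
  schedule (`cooling = 0.97`, `move_factor = 0.25`, 5–10 restarts) and 99
  to 199 null networks: on 130-node networks this reproduces the same
  partitions as the slow default schedule while keeping the whole
  validation run in tens of seconds, and observed and null networks always
  share whatever schedule is in force.
* Problem sizes used in validation: exhaustive modularity oracle on
  networks of ≤ 8 nodes (set-partition enumeration), null-model uniformity
  on a 4×4 incidence fixture (90 fillings, 10,000 draws), pseudo-F/ANOVA
  equivalence on 100 random univariate fixtures, type-I calibration with
  1,000 replicates of 199 permutations, and planted-structure recovery on
  50 paper-scale simulated datasets.

## Limitations

* Modularity is computed on the *binary* network; link weights (read
  counts) are ignored, as are nestedness and specialisation indices.
* The annealer is stochastic; on large networks the returned partition is
  the best of its restarts, not a certified global optimum.
* Habitat, not geography, is the only spatial covariate: the data model
  carries no coordinates, so geographic proximity cannot be separated from
  habitat similarity.
* The indicator test treats populations as exchangeable sites; nesting of
  populations within species is not modelled, so an OTU tied to a single
  widespread species will register as an indicator of that species'
  habitat.
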