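---
title: "Network-based biostratigraphy: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based biostratigraphy: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbiostrat)
```

## The problem

Fossil occurrence compilations record which taxa were found at which
collection points, in which geologic formations, and in which
paleoenvironments. Two distinct kinds of structure are entangled in such
data: *biozones* — sets of roughly age-equivalent formations sharing a
characteristic taxon association, the basic currency of biostratigraphic
correlation — and *biotopes* — associations of taxa restricted to a range of
paleoenvironments (for marine data, positions along a shallow-to-deep
transect). Conventional locality clustering cannot tell these apart, because
environmental restriction, preservational bias, and age all produce
taxonomically distinct clusters.

`netbiostrat` separates the two signals by building different networks from
the same occurrence table and partitioning each into community units:

* a **unipartite genus co-occurrence network** (two genera linked if they
  co-occur at any collection point), whose modules are paleocommunities;
* a **bipartite environments-by-taxa network**, whose modules are biotopes;
* a **bipartite formations-by-taxa network**, whose modules are assemblage
  biozones.

Downstream, biozones are compared by incidence-based rarefaction,
extrapolation, and nonparametric richness estimation, so that a claimed
difference in diversity is defensible against unequal sampling.

## Data model and filtering

An `occurrence_table` normalizes one row per (taxon, collection point) pair;
duplicate reports collapse to a single occurrence. Collection points carry a
formation and geographic metadata; taxa carry a kind (body genus or
ichnogenus), a preservational mode (one of eight taphonomic modes), a
morphogroup (33 groups, body taxa) or trace architecture (24 groups,
ichnogenera), and validity flags. Environment assignment is *per taxon* and
set-valued over the 17 ordered paleoenvironment codes; per-occurrence
environment columns are unioned into the taxon's set on ingest. Controlled
vocabularies live in a packaged YAML file (`load_vocabularies()`) and are
used to report — not reject — unknown codes, since real compilations evolve
faster than their vocabularies.

`filter_index_taxa()` implements the validity policy for taxa counted in
analyses: taxa flagged as simple discs, possible taphomorphs, or possible
pseudofossils are removed, and taxa that never share a collection point nor
a formation with another taxon are removed, since they cannot carry any
network link. The companion rule is applied to a fixed point (a removal can
strand a previously valid taxon), which makes the filter idempotent. Taxon
names are matched exactly after whitespace trimming; no synonymy resolution
is attempted.

## Community detection

Networks are partitioned with an overlapping label-propagation algorithm
(COPRA). Every node starts with its own label at coefficient 1. At each
sweep a node's label map becomes the coefficient-weighted average of its
neighbors' maps; labels below `1/v` are deleted and the rest renormalized;
if every label falls below threshold, one maximum-coefficient label is kept,
with ties broken uniformly at random from the run's seeded stream. The `v`
parameter is thus the maximum number of communities a node may belong to,
and `v = 1` reduces the procedure to crisp label propagation.

Three design choices deserve comment:

* **Update schedule.** Unipartite networks use fully synchronous sweeps. On
  bipartite networks a fully synchronous update oscillates in two phases
  (the initial labels simply swap sides each sweep), which fragments the
  result badly; the package therefore updates the two node classes in
  alternating half-sweeps (one class from the other's previous labels, then
  the reverse). This was adopted after the synchronous variant produced
  systematically fragmented partitions on bipartite benchmarks with planted
  structure.
* **Termination.** After each sweep the per-label node counts are folded
  into running minima; propagation stops when the sorted vector of minima
  repeats a previously seen value (cycle detection), with a hard cap of
  1000 sweeps. The exact window used by the original implementation is not
  published; this criterion is the package's own bounded variant.
* **Extra-simplification.** Communities whose node set is contained in (or
  equal to) another's are removed and coefficients renormalized
  (`extra_simplify()`), applied to every run's output.

Because a single run is cheap and stochastic, `copra_best()` runs many
seeded restarts and keeps the cover with the best score, recording the full
score distribution. Restart seeds derive deterministically from the master
seed, so the best-of-`k` result for any prefix `k` of the stream is
reproducible. The published workflow this package follows used 100,000
restarts per network; the package default is desk-scale (tens to a few
thousand) and the restart count is an explicit argument everywhere.

`v` is chosen by a leave-one-out jackknife (`select_v()`): each node is
removed in turn, the remainder is partitioned crisply (`v = 1`), and the
number of non-singleton communities is recorded; `v` is the maximum count
over all leave-one-out runs.

## Modularity

Crisp partitions are scored with Newman-Girvan modularity
`Q = sum_c [L_c/m - (d_c/2m)^2]`. Overlapping covers are scored with the
product-form extended modularity

`Q_ov = (1/2m) sum_c sum_ij (A_ij - k_i k_j/2m) b_ic b_jc`,

chosen among published belonging-coefficient variants because it reduces
*exactly* to the crisp formula when all coefficients are 1 (this reduction
is enforced at `1e-9` in the test suite, and the formula is the single place
a different variant could be swapped in). Self-loops and multi-edges are
removed before either computation. For bipartite networks, detection runs on
the bipartite graph itself and modularity is evaluated on each one-mode
projection with the induced memberships; restart ranking uses the mean of
the two projection scores. Projections are unweighted (link iff at least one
shared neighbor); a shared-neighbor-count weighting is available but not
used by default, since modularity is reported for simple graphs.

## Statistical validation

**Randomization testing.** `randomize_network()` applies double-edge swaps
(default `10 m` successful swaps) that preserve every node's degree; on
bipartite networks the swap orientation also preserves both classes. The
observed best modularity is compared with `reps` randomized replicates
partitioned identically; `P` is the fraction of null scores at least as
large as the observed one (ties count against the observed structure, and
the observed value is not pooled into its own null), and
`Z = (Q_obs - mean(Q_null)) / sd(Q_null)`.

**Sensitivity analysis.** `sensitivity_profile()` subsamples links at a grid
of retention levels (default 1.0-0.7), re-partitions crisply, and scores
agreement with the reference partition by NMI, with every omitted node
counted as its own singleton module. The matched null pairs two
degree-preserving randomizations — one of the network, one of the
subnetwork — partitioned the same way; a level is called robust when at
least 95% of observed NMI scores exceed their matched nulls.

**NMI.** Shannon mutual information with sum normalization
`2I/(H_a + H_b)` (the common library default; `max` and `sqrt` forms are
available). Two identical single-cluster partitions define NMI = 1.

## Diversity comparison of biozones

Samples are formations or collection points; the data are incidences
(presence/absence). `rarefy_incidence()` uses the closed-form sample-based
expectation `S(n) = S_obs - sum_i C(N - Y_i, n)/C(N, n)`, with the
unconditional moment variance
`var(n) = sum_i (1 - alpha_i)^2 - S(n)^2 / S_chao2`, which stays positive at
`n = N` (the reference sample is treated as itself random). Extrapolation
follows the Chao2-based form
`S(N + m) = S_obs + Q0 (1 - (1 - Q1/(Q1 + N Q0))^m)`, flat when `Q1 = 0`
and tending to the Chao2 asymptote. Richness estimators implemented are
classic Chao2 (bias-corrected when `Q2 = 0`, with the classic analytic
variance), jackknife-1/2, bootstrap, and ICE with the conventional
infrequent threshold of 10 samples. Estimator curves versus sampling
intensity use subsampling without replacement; their conditional CIs are
empirical quantiles that collapse at full sampling, while Chao2 additionally
carries an unconditional analytic CI. The analytic unconditional variance
for jackknife-2 used by some richness software is not published in a form
this package could verify, so jackknife-2 intervals here are conditional
(iterated) only. Extrapolation CIs come from a taxon-resampling bootstrap.

Two biozones are compared at the current sampling level of the
less-sampled one: non-overlapping unconditional 95% CIs reject equal
richness; touching intervals count as overlap (conservative).

Clustering of formations uses binary Kulczynski-2 (default) or Jaccard
dissimilarity, average-linkage (UPGMA) merging with labels pre-sorted so tie
merges are deterministic, cophenetic correlation as the distortion summary,
and plain bootstrap proportions (taxon resampling) for clade support.
Multiscale-bootstrap AU corrections are deliberately out of scope; plain
support proportions are reported and labelled as such.

## The synthetic generator

`generate_occurrences()` plants known structure so every stage can be scored
against ground truth: `K` biozones each own a pool of taxa plus a fraction
drawn from a shared pool; formations belong to one biozone and carry a
contiguous window on the environment gradient, with window starts cycled
across each biozone's formations so that every biozone collectively samples
the whole gradient (otherwise a biozone could structurally miss a biotope
and its taxa would be unobservable there); collections draw an
environment from their formation's window and sample environment-compatible
taxa from the biozone pool — without replacement, weighted by lognormal
per-taxon occupancy weights — each detected with probability
`detection_probability`. Taxon environment sets are the realized ones, just
as in real compilations.

Default conditions: 4 biozones x 10 formations, 45 taxa per pool (about 180
realized taxa), 10-20 collections per formation (about 600 points), 2-5
taxa recorded per collection, 10% shared pool, detection 0.9, occupancy
sdlog 1.2. The occupancy skew and the 2-5 taxa per collection were set to
match the density of real global compilations (roughly three occurrences
per collection point and a strongly right-skewed occupancy distribution);
without the skew the generated formation projections are unrealistically
dense and no rare taxa exist for the richness estimators to use. What the
generator does *not* emulate: taphonomic bias interacting with environment,
stratigraphic age models, spatial autocorrelation, and taxonomic noise —
so green recovery tests demonstrate algorithmic correctness under the
planted model, not performance guarantees on any particular real dataset.

Biozone recovery is scored on formation nodes (`recovery_score()`), whose
planted label is single-valued; shared taxa genuinely belong to several
biozones and would impose an artificial ceiling on a taxon-level NMI.

## Numerical conventions and degenerate inputs

* Link counts in subsampling round half-up; `fraction = 1` is the identity.
* Modularity is undefined on edgeless networks and is signalled as an
  error; undefined assortativity (zero variance; regular graphs, constant
  attributes) warns and returns `NA` rather than silently returning 0.
* Rigid degree sequences (triangles, complete bipartite 2x2) cannot be
  rewired; the randomizer returns the input with a warning.
* Chao2 and jackknife-1 never fall below `S_obs`; jackknife-2 can, when
  doubletons dominate singletons — that is a property of the estimator, not
  clamped away here.
* Isolated nodes become reported singleton communities; a Cover's
  coefficients sum to 1 per node within `1e-9` and are validated in tests
  after every propagation sweep.
* All stochastic operations take explicit integer seeds; per-restart and
  per-stage seeds are derived from the master seed by a fixed integer
  recurrence, so whole pipeline runs are reproducible checksum-for-checksum.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run on the default synthetic
conditions above (about 600 collections, 170-190 network nodes) with
desk-scale restart budgets: 10-50 restarts for detection, one restart per
leave-one-out run during `v` selection, 50 randomization replicates, and 20
sensitivity repetitions. These are the package's chosen demonstration
scales; all budgets are arguments that scale up for production analyses.

## Known limitations

* COPRA is the only community-detection algorithm provided (with a crisp
  `v = 1` path); comparative algorithm benchmarking is out of scope.
* Weighted-network propagation is not implemented.
* NMDS ordination and AU-corrected bootstrap support are out of scope by
  design; the clustering stage alone carries the dendrogram analyses.
* The per-projection modularity reported for bipartite covers depends on
  the (unweighted) projection convention; weighted projections would give
  different absolute values.
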