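# netbiostrat

Network-based biostratigraphy for fossil occurrence data.

## The problem

Global compilations of fossil occurrences mix several kinds of structure:
formations of similar age share taxa (**biozones**, the units that let
geologists correlate strata), environments of similar depth share taxa
(**biotopes**), and preservation pathways bias what is recorded at all.
Conventional locality clustering produces taxonomically distinct groups but
cannot say which of these signals it found. `netbiostrat` separates them by
building different networks from the same occurrence table and partitioning
each into community units:

| network | nodes | modules represent |
|---|---|---|
| unipartite co-occurrence | genera | paleocommunities |
| bipartite | environments × taxa | biotopes |
| bipartite | formations × taxa | assemblage biozones |

The package is aimed at paleoecologists and biostratigraphers working with
occurrence tables (PBDB-style collections), but the community-detection and
validation machinery is generic network methodology.

## The core method

Networks are partitioned with **COPRA**, an overlapping label-propagation
algorithm: every node carries a map of community labels with belonging
coefficients `b_ic` summing to 1; each sweep replaces a node's map with the
average of its neighbors' maps, deleting labels below `1/v` (the parameter
`v` caps how many communities a node may join). `v` itself is selected by a
leave-one-out jackknife over nodes. Covers are scored with extended
(overlap) modularity

```
Q_ov = (1/2m) Σ_c Σ_ij (A_ij − k_i k_j / 2m) b_ic b_jc ,
```

which reduces exactly to Newman–Girvan `Q` for crisp partitions. Observed
structure is validated two ways: against degree-preserving rewired null
networks (one-sided `P` and `Z` on modularity) and by link-subsampling
sensitivity profiles scored with normalized mutual information (omitted
nodes count as their own singleton modules). Detected biozones are then
compared with sample-based rarefaction/extrapolation and nonparametric
richness estimators (classic Chao2, ICE, jackknife-1/2, bootstrap) with
unconditional confidence intervals, so richness differences are defensible
against unequal sampling.

A synthetic occurrence generator with planted biozone/biotope structure
(`generate_occurrences()`) provides ground truth for every stage.

## Worked example

```r
library(netbiostrat)

gen   <- generate_occurrences(synthetic_config(seed = 42))
tab   <- filter_index_taxa(gen$table)         # index-taxa validity policy
net   <- bipartite_network(tab, "formations") # formations x taxa
v     <- select_v(net, seed = 42, restarts_per_leave = 1)$v
cover <- copra_best(net, v = v, restarts = 50, seed = 42)

print(gen$table)
#> <occurrence_table>
#>   occurrences: 2229
#>   taxa: 168 (157 body genera, 11 ichnogenera)
#>   collection points: 628
#>   formations: 40
print(cover)
#> <copra_cover> v = 9 | 4 communities over 200 nodes
#>   sizes: 54, 53, 53, 51
round(projection_modularity(net, cover), 3)
#>     taxon formation
#>     0.631     0.138
recovery_score(cover, gen$truth, "biozone")
#> [1] 1
```

The generator planted 4 biozones; the jackknife picked `v = 9`, COPRA found
exactly 4 modules, and the detected formation grouping matches the planted
one perfectly (NMI = 1). The taxa-projection modularity 0.631 says the taxon
side is strongly block-structured; `modularity_significance()` turns such a
number into `P`/`Z` against degree-matched random networks. Richness
estimators on the same data (`richness_estimators(build_incidence(tab,
"collection_point"))`) bracket the ~168 realized taxa:

```
   estimator estimate
1      chao2 169.3739
2        ice 164.2946
3 jackknife1 172.9793
4 jackknife2 176.9809
5  bootstrap 166.9137
```

`run_pipeline(run_config(...))` chains the whole analysis (ingest → filter →
networks → v-selection → detection → significance → sensitivity → metrics →
clustering → rarefaction) and writes CSV/JSON/GraphML/Newick outputs plus a
manifest with seeds and checksums; `inst/cli/netbiostrat.R` is a thin
command-line wrapper.

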