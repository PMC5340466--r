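# heattree

Community surveys that classify records against a taxonomic hierarchy —
16S/18S metabarcoding, OTU tables, even non-biological hierarchies like
gene ontologies — are awkward to handle with flat tables: filtering a
taxon says nothing about what should happen to its subtaxa and its
sequences, per-taxon summaries go stale the moment rows are dropped, and
stacked bar charts cannot show how a statistic distributes across ranks.
`heattree` is an R package for ecologists and bioinformaticians facing
exactly this: it provides a hierarchy-aware data object, a universal
parser for taxonomy-bearing text, manipulation verbs that respect the
hierarchy, a native in-silico PCR engine for primer evaluation, a
two-group differential-abundance test, and quantitative **heat trees** —
taxonomic trees whose node and edge color and size encode per-taxon
statistics, with honest legends.

## What is inside

* **`Taxmap`** — an S4 object coupling a taxon edge list (forest) with an
  observation table, plus computed columns (e.g. `n_obs`, the number of
  observations in each taxon's subtree) that are re-evaluated on every
  access and so can never be stale. Traversals: `roots()`, `subtaxa()`,
  `supertaxa()`, `observations()`.
* **Universal parsing** — `parseRecords()` / `parseFasta()` turn any
  regex-definable format (Greengenes/SILVA/RDP-style headers,
  `k__Bacteria;p__Firmicutes` lineage strings, tables) into a `Taxmap`,
  deduplicating shared lineage prefixes into a single edge list.
* **Hierarchy-aware verbs** — `filterTaxa()` (with explicit control over
  subtaxa, supertaxa, re-parenting and observation reassignment),
  `filterObs()`, `mutate/transmute/select/arrange` for both tables,
  weighted `sampleNTaxa()`/`sampleNObs()` and rank-targeted
  `taxonomicSample()`.
* **Digital PCR** — `digitalPcr()` matches IUPAC degenerate primers
  (codes match when their base sets intersect) under a mismatch budget of
  `floor(p/100 · L)` positions, pairs forward sites with downstream
  reverse sites, predicts product coordinates, and summarizes the
  proportion of sequences amplified per taxon.
* **Two-group comparison** — `compareTreatments()` computes, per taxon,

  `log2( median_a(proportion) / median_b(proportion) )`,

  a two-sided Wilcoxon rank-sum p-value (exact for ≤ 12 observations
  without ties, normal approximation with tie and continuity correction
  otherwise) and a Benjamini–Hochberg adjusted p-value; the gated ratio
  (`0` where `p_adj ≥ α`) maps straight onto node color so only
  significant differences are colored.
* **Heat trees** — `heatTree()` lays out one sub-tree per root
  (Reingold–Tilford layered layout, or seeded Fruchterman–Reingold),
  optimizes the node size range so disc overlap stays under 1% of total
  disc area, maps statistics to sizes and colors through monotone affine
  / piecewise-linear-RGB maps, and writes byte-deterministic SVG (plus
  PDF/PNG) whose normalized geometry is independent of output pixel size.
  Legend tick/value pairs are also emitted as JSON.
* **Synthetic fixtures** — `randomTaxmap()`, `randomSequences()` (with
  plantable primer sites and injected mismatches) and
  `randomAbundance()` (log-normal baseline, plantable fold-changes)
  generate fully ground-truthed test data; everything runs offline.

## Worked example

Build a small classified sequence set, evaluate a common 16S primer pair
in silico, test two sample groups against each other, and draw the
result:

```r
library(heattree)

fx <- randomTaxmap(nTaxa = 12, nObs = 40, maxDepth = 3,
                   ranks = c("domain", "phylum", "genus", "species"), seed = 8)
pp <- primerPair("GTGCCAGCMGCCGCGGTAA", "GGACTACHVGGGTWTCTAAT", 10)
sq <- randomSequences(40, seqLength = 150, primers = pp,
                      plantedFraction = 0.75, seed = 9)
tm <- digitalPcr(mutateObs(fx$taxmap, sequence = sq$sequences), pp)
head(pcrSummary(tm), 4)
#>   taxon_id    name n_obs n_amplified n_not_amplified prop_amplified
#> 1      t_1 taxon_1    40          30              10      0.7500000
#> 2      t_2 taxon_2    21          17               4      0.8095238
#> 3      t_3 taxon_3    13          10               3      0.7692308
#> 4      t_4 taxon_4    19          13               6      0.6842105
```

30 of 40 sequences amplify — the planted 75% binding-site fraction —
and `prop_amplified` is a computed column, so it stays correct after any
filtering. Now plant a 4-fold enrichment of taxon `t_4` in group B and
test:

```r
ab <- randomAbundance(taxonIds(tm), nPerGroup = 10,
                      effectTaxa = c(t_4 = 4), seed = 10)
cmp <- compareTreatments(tm, ab$counts, ab$treatments, "A", "B")
cmp$result[cmp$result$taxon_id == "t_4", c("log2_ratio", "p_adjusted")]
#>   log2_ratio   p_adjusted
#> 4  -1.908704 0.0005480154
```

The planted taxon comes back with a strongly negative A-over-B log2
ratio (about −1.9, i.e. ~3.8-fold up in B at the proportion scale) and a
tiny adjusted p-value. Note that the other taxa pick up small *positive*
significant ratios: proportions are compositional, so enriching one
taxon necessarily depresses the rest — a property of proportion-based
testing worth keeping in mind, not a bug. Finally:

```r
ht <- heatTree(cmp$taxmap, nodeSize = n_obs, nodeColor = log2_ratio_gated,
               colorInterval = c(-3, 3), output = "tree.svg")
ht$legend$node_color
#> $ticks
#> [1] -2  0  2
#> $mapped
#> [1] "#6896C5" "#F7F7F7" "#C9626E"
```

`tree.svg` shows the taxonomy with node size proportional to `n_obs` and
the significance-gated ratio on a blue–white–red diverging scale centered
at zero; `tree.svg.legend.json` carries the same legend metadata for
programmatic checks.

A thin CLI over the same functions lives at `inst/cli/heattree-cli.R`
(`make-fixture`, `parse`, `filter-taxa`, `filter-obs`, `digital-pcr`,
`heat-tree`, `compare`), moving data between steps as a TSV pair per
directory.

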