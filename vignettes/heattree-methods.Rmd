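---
title: "Models and methods behind heattree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heattree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattree)
```

## The Taxmap data model

Metabarcoding and other community surveys produce records — sequences,
OTUs, annotations — that are classified against a taxonomic hierarchy.
`heattree` stores such data as a `Taxmap`: two coupled tables plus a
registry of column-generating functions.

* The **taxon table** is an edge list encoding a forest. Each row has a
  unique, opaque `taxon_id`, a `supertaxon_id` (`NA` for roots), a `name`
  and an optional free-form `rank`. Ranks are deliberately *not* validated
  against a fixed vocabulary: reference databases disagree on rank names,
  and the parser must accept all of them.
* The **observation table** maps each record (`obs_id`) to exactly one
  taxon. An observation may sit on an internal taxon that also has
  subtaxa — classifiers frequently stop above species level, so forbidding
  internal assignment would misrepresent real data.
* **Computed columns** are functions of the whole object, re-evaluated on
  every access. `n_obs` (observations in a taxon's subtree) is registered
  by default; `digitalPcr()` adds `n_amplified`, `n_not_amplified` and
  `prop_amplified`. Storing such quantities as static columns would leave
  them silently stale after filtering or subsampling; recomputation makes
  staleness impossible by construction. If a user column shares a name
  with a computed column, the user column wins and a warning is emitted.

Taxon IDs are assigned as `t_<k>` in first-seen order at parse time and
are never renumbered by later operations: a filtered object's IDs are a
subset of the original's, which keeps provenance trivial to track and
makes every manipulation testable against set-based oracles.

All set-valued traversal results (`roots`, `subtaxa`, `observations`)
come back in taxon-table row order; `supertaxa` returns nearest ancestor
first. The contract is arbitrary but fixed — a deterministic order makes
every downstream result reproducible. `arrangeTaxa()`/`arrangeObs()`
therefore change presentation and result ordering, never which elements a
traversal returns.

## Universal parsing

`parseRecords()` converts any text format definable by a regular
expression into a `Taxmap`. The `ParseSpec` pairs the regex with a key
naming the role of each capture group (`class`, `taxon_name`, `taxon_id`,
`obs_info`). A `class` capture is split on a level separator and
optionally a rank separator (`"k__Bacteria"`), root-most level first;
`reverseLevels = TRUE` accommodates leaf-first formats.

Taxon identity during deduplication is the **full root-to-taxon path** of
(name, rank) pairs, not the bare name: two taxa called
`Incertae_sedis` under different parents remain distinct. Path identity
is the only rule under which the merged edge list is always a
well-defined forest. When the same path arrives with conflicting rank
labels, the first-seen rank is kept and a warning records the conflict.
Whitespace around level names is stripped; empty levels (`";;"`) are
dropped with a warning.

`writeLineages()` renders the inverse mapping, and
`parseRecords(writeLineages(tm))` reconstructs an isomorphic object —
the round-trip property the test suite checks on hundreds of random
taxonomies. Rendering refuses separators that occur inside names (the
output would not re-parse unambiguously), and a rank separator requires
every rendered taxon to carry a rank for the same reason.

Classification lookups in online databases by taxon or sequence ID are
deliberately out of scope; the parser consumes local text only. A
`taxon_id` capture is stored verbatim as the taxon column `external_id`.

## Hierarchy-aware manipulation

Filtering a hierarchy is ambiguous until one decides what happens to the
relatives of removed taxa. `filterTaxa()` makes every choice explicit:

1. select taxa passing the predicate;
2. expand with `keepSubtaxa` / `keepSupertaxa` (descendants/ancestors);
3. `invert` complements the set *after* expansion (one fixed rule);
4. survivors whose parent was removed are re-parented to their nearest
   surviving ancestor when `reassignTaxa = TRUE`, otherwise become roots;
5. observations of removed taxa move to their nearest surviving ancestor
   when `reassignObs = TRUE`, otherwise they are dropped.

The defaults (`keepSubtaxa = FALSE`, `keepSupertaxa = FALSE`,
`reassignObs = TRUE`, `reassignTaxa = TRUE`) preserve data unless the
caller opts out. Every verb returns an object that passes the full class
validator; the test suite checks all 16 flag combinations against an
independent set-based oracle on hundreds of random forests.

Weighted sampling without replacement (`sampleNTaxa`, `sampleNObs`) is
defined as *sequential renormalized draws*: each successive pick is
proportional to the remaining weights. This definition is stated rather
than left to a library default because it makes the sampling distribution
exactly enumerable, so tests can compare empirical inclusion frequencies
against closed-form probabilities. Every stochastic operation takes an
explicit `seed` and restores global RNG state afterwards.

`taxonomicSample()` balances representation at one rank: taxa at the
target rank with fewer than `minCounts` recursive observations are
removed subtree-and-all (exclusion, not truncation), and those with more
than `maxCounts` are uniformly subsampled down to exactly `maxCounts`.
Observations not under any taxon of the target rank are untouched.

## In-silico PCR

`digitalPcr()` predicts amplification success natively. Two IUPAC codes
match when their base sets intersect (`N` matches anything; `A` matches
`R` but not `Y`); a primer binds at an ungapped offset where the number
of non-matching positions is at most `floor(p/100 * L)` for budget `p`
percent and primer length `L` — the floor mirrors the percent semantics
commonly used by primer-search tools. An observation amplifies when a
forward site exists and a reverse site (the reverse complement of the
reverse primer) starts at or beyond the forward site's end; the product
spans forward start to reverse end. Among qualifying site pairs the
shortest product wins, ties going to the leftmost forward site — an
arbitrary but fixed rule, chosen because the shortest amplicon dominates
real PCR kinetics.

Only the given orientation of each template is scanned by default, since
reference databases are orientation-normalized; `bothStrands = TRUE`
also scans the reverse complement and accepts a hit on either strand.
Degenerate `N` positions in templates match any primer base, consistent
with set-intersection matching. No thermodynamic modelling, primer-dimer
checks or gapped alignment is attempted.

`prop_amplified` is amplified-in-subtree over `n_obs`; for a taxon with
no observations anywhere below it the proportion is undefined and
reported as `NA` (plots draw such taxa in neutral gray).

## Two-group comparison

`compareTreatments()` reproduces the standard differential-abundance
recipe: per-sample read proportions (each sample column divided by its
sum — no subtree re-normalization), per-taxon log2 ratio of the two group
medians, a two-sided Wilcoxon rank-sum p-value per taxon, and
Benjamini–Hochberg adjustment across all tested taxa. `log2_ratio_gated`
zeroes the ratio wherever `p_adjusted >= alpha` (default 0.05), so
mapping it onto node color yields plots where only significant
differences are colored.

The Wilcoxon p-value is exact (permutation-null) when the combined
sample size is at most 12 with no ties, otherwise the normal
approximation with tie and continuity correction is used; the test suite
documents the size of that approximation step (below 0.02 for group
sizes 8–12) rather than hiding it. Two identical samples return p = 1.
Zero medians need a policy: both zero gives ratio 0; exactly one zero
gives a capped ratio one unit beyond the largest finite magnitude among
the tested taxa, flagged in `ratio_capped`. Taxa tested are exactly the
rows of the supplied matrix — no prevalence pre-filter is applied.

The comparison columns are merged into the taxon table as static columns
rather than registered functions: their values depend on the external
abundance matrix, and a registered function would silently desynchronize
from it if the matrix changed.

## Heat trees

`heatTree()` maps up to four per-taxon statistics onto node/edge size
and color. Numeric choices worth knowing:

* **Layout.** Reingold–Tilford layered layout by default (children
  centered under parents, sibling subtrees on disjoint extents);
  Fruchterman–Reingold force-directed layout as a seeded, reproducible
  alternative initialized from the layered coordinates. One layout per
  root; multiple roots are arranged in a near-square grid
  (`ncol = ceiling(sqrt(k))`).
* **Size mapping.** `mapAesthetic()` is an affine map of (optionally
  `log10`/`sqrt`-transformed) values onto a radius interval; a constant
  column maps to the interval midpoint. The interval itself comes from
  `optimizeSizeRange()`: the largest maximum radius (minimum fixed at a
  quarter of the maximum) such that total pairwise disc-overlap area
  stays within 1% of total disc area, found by 20 bisection iterations.
  The 1% tolerance makes the informal goal "minimize overlap, maximize
  size" explicit and testable; if even the smallest candidate radius
  violates it, that candidate is used.
* **Color mapping.** Channel-wise linear interpolation in RGB through
  the palette anchors; an odd anchor count places the middle anchor at
  the interval midpoint, which is what a diverging palette around zero
  needs. Values outside an explicit interval clamp to the endpoints.
  RGB interpolation keeps the mapping trivially checkable; a perceptual
  space would be a possible extension, not the default.
* **Output.** SVG is written directly with a fixed 1000-unit viewBox and
  fixed-precision coordinates, so a given (input, spec, seed) produces a
  byte-identical file and changing the requested pixel size changes only
  the width/height attributes — the plot looks the same at any output
  size. Legends report tick values alongside their mapped sizes/colors,
  and the same metadata is written as `<output>.legend.json` so the
  value-to-aesthetic relationship can be verified programmatically.
  Labels that overflow their node are shrunk to a floor size and then
  truncated with an ellipsis. Edges taper linearly between the two
  adjacent nodes' widths. PDF/PNG outputs draw the same normalized
  geometry on grDevices devices.

Circular or radial layouts, interactive output and phylogenetic edge
lengths are out of scope: these are taxonomic trees, where an edge
records classification, not evolutionary distance.

## The synthetic-data generators

Every module is testable offline because the fixtures are generated, with
the generating ground truth returned alongside the data:

* `randomTaxmap()` grows a forest by sequential parent attachment under a
  depth cap, with parents holding fewer than `branching` children
  preferred (defaults: 30 taxa, 60 observations, depth 4, branching 2 —
  the shape of a moderately deep reference taxonomy). Ranks are assigned
  by depth; observations land on uniformly chosen taxa, internal ones
  included.
* `randomSequences()` draws i.i.d. uniform A/C/G/T templates and can
  plant a forward site and a strictly downstream reverse-complemented
  reverse site at recorded positions, with a recorded number of injected
  mismatches — the truth table the PCR oracle tests consume.
* `randomAbundance()` draws log-normal baseline weights
  (`sdlog = 1.5`, a long-tailed rank-abundance shape typical of
  microbiome communities) and multinomial per-sample counts (default 10
  samples per group, 10 000 reads each); fold-changes are planted in
  group B only and recorded.

What the generators deliberately do **not** emulate: real database
taxonomy shapes beyond these parameters, sequence composition bias,
chimeras, overdispersion beyond the multinomial, or sample-to-sample
library-size variation. Passing tests therefore demonstrate correctness
of the algorithms under controlled conditions, not robustness to every
artifact of real survey data.

## Problem sizes used by the property suites

The shipped suites exercise: 1000 random forests (up to 200 taxa and 500
observations) for the traversal oracles; 200 forests × all 16 flag
combinations for filtering; 200 taxonomies for the parser round trip;
500 planted-site templates for digital PCR; 1000 random p-vectors for
the BH oracle, 500 null datasets (30 taxa, 10 vs 10 samples) for type-I
control and 200 replicates for planted-effect recovery; and 30 000
replicates of a five-item weighted draw. `scripts/acceptance.R` re-runs
the same suites from scratch and writes the measured agreement rates to
JSON.

## Known limitations

* Predicate expressions are evaluated with standard R scoping against
  the materialized table; there is no quoting/unquoting machinery beyond
  that.
* `filterTaxa` recomputes ancestor walks per call; on taxonomies of
  millions of taxa an indexed implementation would be preferable.
* The Wilcoxon exact route enumerates only through the standard null
  distribution (no ties); tied exact p-values fall back to the corrected
  normal approximation.
* SVG text metrics are approximated (no font shaping), so label
  truncation is conservative rather than typographically exact.
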