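Package: heattree
Title: Taxonomic Hierarchies, In Silico PCR and Quantitative Heat Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for community data organized on a taxonomic hierarchy.
    Provides the Taxmap class, an edge list of taxa coupled to a table of
    observations (sequences, OTUs, or any records assigned to taxa) with
    lazily computed columns; a regex-driven universal parser that turns
    FASTA headers or lineage strings in arbitrary formats into a Taxmap;
    hierarchy-aware filter/select/mutate/arrange/sample verbs; a native
    in-silico (digital) PCR engine for IUPAC degenerate primers under a
    mismatch budget; per-taxon two-group comparison (log2 ratio of median
    read proportions, Wilcoxon rank-sum test, Benjamini-Hochberg
    correction); and "heat tree" plots that map up to four per-taxon
    statistics onto the color and size of tree nodes and edges, with
    quantitative legends, automatic size-range optimization and one
    sub-tree per root.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
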