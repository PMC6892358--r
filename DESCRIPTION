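Package: syntenykit
Title: Anchor-Based Conserved Synteny Blocks and Annotation-Driven
    Feature Filtering for Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects framed, collinear blocks of conserved synteny between two
    genomes from ortholog gene-pair anchors, and supports candidate-gene
    queries inside syntenic regions.  Ingests gene models from GFF3,
    ortholog pairs as two-column tables, ontologies (GO, MP, DO) from OBO
    and gene-term annotations from GAF2; computes synteny blocks by scanning
    maximal runs of sequential ortholog indices; reads and writes a
    ten-column tab-delimited block format; maps reference intervals to
    their comparison-genome counterparts; and filters genome features in a
    displayed region by symbol, feature type or ontology term with Boolean
    combination, genome scoping and ortholog-aware match provenance.
    Includes deterministic simulators for genome pairs with planted
    rearrangements, and a single-file embedded data store with JSON query
    endpoints and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
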