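---
title: "Detecting conserved synteny blocks and filtering features by annotation"
author: "syntenykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved synteny blocks and filtering features by annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenykit)
```

## The model

`syntenykit` detects *framed, collinear* blocks of conserved synteny
between two genomes.  The model deliberately uses gene order only, never
DNA alignment: the input is each genome's gene models (GFF3, 1-based
inclusive coordinates) and an orthology relation given as a binary
relation of gene pairs.  After reducing the relation to one-to-one, each
genome's anchored genes are sorted by chromosome and start position and
numbered from 1.  Scanning the reference genome's anchors in ordinal
order, each maximal run in which the comparison ordinal steps by exactly
+1 or −1 — with neither genome's chromosome changing — is one block,
oriented `+` if the comparison indices increase and `−` (an inversion) if
they decrease.  Block boundaries are the outer limits of the member
genes, so a block's span is determined entirely by its anchors.

Assumptions worth making explicit:

* **Strictly consecutive indices.**  "Sequential" is read as |Δ| = 1.
  This is the framed-collinear reading: a block tolerates no interleaved
  anchor from elsewhere.  A relaxed mode (`mode = "monotonic"`, any step
  of constant sign) exists for exploration but is not the default.
* **Only anchored genes get ordinals.**  Genes without a surviving
  ortholog pair are invisible to the scanner; an unannotated or
  lineage-specific gene therefore never shatters a block.  Were ordinals
  assigned to all genes, almost every genome pair would collapse into
  two-anchor fragments.
* **Strand is ignored.**  Inversion status is carried by the index
  direction, not by gene strand, so blocks are well defined even when
  strand annotation is unreliable.
* **Runs break at chromosome changes in either genome**, since a block
  is by definition a contiguous chromosomal segment on both sides.

## Parameters

* `min_anchors` (default **2**): a run of length 1 has no second index
  and thus no defined direction; singleton runs are dropped by default
  and emitted with orientation `+` only if `min_anchors = 1` is
  requested explicitly.
* `multi_policy` (default **`drop_ambiguous`**): the scanner needs a
  function from reference ordinals to comparison ordinals, so
  one-to-many orthology must be resolved.  `drop_ambiguous` removes every
  pair touching a multi-mapped gene — conservative, and symmetric in the
  two genomes.  `keep_first_by_position` instead keeps, scanning
  position-ordered pairs greedily, the first pair per gene; it retains
  more anchors at the cost of an upstream-partner bias.  Both yield a
  one-to-one relation; tests verify injectivity directly.
* Ties in the ordering key (identical chromosome and start) are broken
  by end coordinate, then feature ID, making ordinals — and therefore
  blocks and block IDs — fully deterministic.
* Block identifiers are `SynBlock:<tag>:<n>` with `n` counting along the
  reference; `<tag>` defaults to concatenated taxon shorthands
  (`mmhs` for mouse→human).

Coordinates are 1-based inclusive everywhere, following GFF3; the block
file format inherits this convention.  Chromosome names are stored
without a `chr` prefix (readers strip it), matching the bare names used
in the block format.

## Ontology closure and annotation semantics

Term searches use descendant closure: a query for a term retrieves
features annotated to the term *or any descendant* along `is_a` and
`part_of` edges — the standard true-path convention, and the reason a
search for a general process term finds genes annotated only to its
specializations.  Other relationship types (e.g. `regulates`) are not
followed.  All evidence codes are accepted, including IEA; rows with a
`NOT` qualifier are excluded from positive retrieval and kept in a
separate negative table.  MP and DO association files are read by the
same 17-column GAF reader, routed to their ontology by name.  Term input
is accepted as an ID, a case-insensitive exact name, or a synonym.

Closure-on is the default (a `descendant_closure()`-free search can be
emulated by querying leaf terms); the worked gene lists the package
replays plausibly include descendant-term annotations, and retrieval
anti-monotonicity (ancestors retrieve supersets) is tested end to end.

## Filter scope and provenance

The display filter evaluates symbol, feature-type and term clauses over
the features of a displayed region: the reference side is a coordinate
window, while the comparison side is *block-driven* — the features under
the comparison spans of blocks overlapping the region — because that is
what a syntenic detail view actually shows.  Under `scope = "either"` a
feature matches either through its own attributes (`self`) or through an
ortholog's (`via_ortholog`).  Under `scope = "reference"` or
`"comparison"` clauses are evaluated against that genome only, but
matches are still projected onto the other genome through orthology,
with provenance recording which side supplied the evidence; this mirrors
highlighting both tracks of a browser.  Boolean combination is a single
top-level AND/OR over clauses rather than an arbitrary expression tree —
the shape a filter panel produces, and trivially extensible.  The
`exclude_nonmatching` toggle is pure display metadata and never alters
the match set.

## What the simulators emulate — and what they do not

`simulate_genome_pair()` plants inversions and translocations with
breakpoints always *between* genes, on evenly spaced, non-overlapping
gene spans, so the true block decomposition is known by construction:
each maximal stretch of the rearranged genome carrying consecutive
source indices on a single chromosome pair is one block.  The use-case
bundles embed the two candidate-gene searches the package replays: a
human 6:130,300,000–161,000,000 susceptibility interval with an inverted
mouse segment, and the mouse T2dm2sa QTL
(chr2:29,417,935–148,533,014, GRCm38) with two human syntenic blocks.
Published coordinates are used where they exist (the QTL span, the
chromosome-6 interval); all other fixture coordinates are synthetic and
deliberately round, so tests count genes and never compare invented
base-pair positions.  Toy ontologies give every queried term one parent
and one child so closure is always exercised.

What passing these tests does *not* show: real ortholog sets contain
paralog tangles, assembly gaps, and micro-rearrangements below gene
resolution; real ontologies are far deeper; and real annotation sets are
incomplete in ways the simulator does not model.  The simulators
validate the algorithmic machinery, not biological completeness.

One source discrepancy is carried as-is: the diabetes use case's
impaired-glucose-tolerance search is described in its source as
returning thirteen genes but lists twelve symbols; the fixture encodes
the twelve listed symbols and the package makes no claim about the
thirteenth.  Similarly, the worked block record's reference start is
typeset ambiguously in its source; the package uses 3205901 and its
checks rely only on the unambiguous comparison-side fields.

## Numerical and design choices

* **Degenerate inputs.**  An empty anchor set yields an empty block list
  (not an error); a region in a synteny gap yields an empty comparison
  display with a warning; an absent chromosome in a region query warns
  and returns nothing.
* **Determinism.**  Every sort has a total-order key ending in a feature
  or block ID; repeated calls are byte-identical, and all simulators take
  seeds and restore the caller's RNG state.
* **Interval mapping granularity.**  `map_region()` reports the full
  block span and the anchor hull of the overlapped sub-region, with no
  base-pair interpolation inside blocks — the block model defines no
  within-block coordinate correspondence, and pretending otherwise would
  manufacture precision.
* **Storage.**  `etl_load()` runs its four loaders in a fixed order
  (features + blocks, ontologies, annotations, configuration) and writes
  one self-contained single-file store with provenance (sources, row
  counts, timestamp).  Re-running replaces the store, so loading is
  idempotent.  Endpoints are read-only and versioned with a
  `schema_version` field; the endpoint documents are the JSON
  serializations of the corresponding library results, a property the
  tests assert literally.  The JSON endpoints are exposed as library
  calls and CLI subcommands; an HTTP wrapper was left out of scope since
  it would add deployment surface without adding queryable behaviour.
* **Problem sizes in the test suite** were chosen to exercise every code
  path at speed: 1,000 random permutations of up to 50 anchors for the
  scanner/oracle comparison, 100 planted scenarios of 30 genes on 3
  chromosomes with up to 5 inversions and 3 translocations, and 100
  random 200-term ontologies for closure checking.

## Known limitations

* Synteny is pairwise only; no multi-genome chaining.
* No block merging across small interruptions: a single interleaved
  anchor splits a block, by design of the framed-collinear model.
* One-to-many orthology is resolved, not modelled; gene family
  expansions are therefore under-counted as anchors.
* Filter expressions are flat AND/OR; nested Boolean logic would need an
  expression-tree front end (the engine's clause evaluation would not
  change).
* QTL and other span features participate in region queries and filters
  but are not anchors (they have no orthologs).
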