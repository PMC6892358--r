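test_that("display set resolution is block-driven on the comparison side", {
  lg <- get_lung()
  # region strictly inside the inverted chromosome-6 block
  reg <- region_selection(9606, "6", 131e6, 140e6)
  ds <- resolve_display_set(reg, lg$blocks, lg$ref, lg$comp)
  blk <- lg$blocks[lg$blocks$ref_chr == "6" & lg$blocks$orientation == "-", ]
  hit <- blk[blk$ref_start <= reg$end & blk$ref_end >= reg$start, ][1, ]
  manual <- lg$comp[lg$comp$chromosome == hit$comp_chr &
                    lg$comp$start <= hit$comp_end &
                    lg$comp$end >= hit$comp_start, ]
  expect_setequal(ds$comparison$feature_id, manual$feature_id)

  # a region in a synteny gap has an empty comparison side
  expect_warning(
    gap <- resolve_display_set(region_selection(9606, "6", 1, 2),
                               lg$blocks, lg$ref, lg$comp),
    "no synteny block")
  expect_equal(nrow(gap$comparison), 0)
})

test_that("a region spanning blocks on two comparison chromosomes unions them", {
  t2 <- get_t2dm()
  ds <- t2$ds
  expect_setequal(unique(ds$comparison$chromosome), c("2", "11"))
  # brute-force union over all overlapping blocks
  hit <- t2$blocks[t2$blocks$ref_chr == "2" &
                   t2$blocks$ref_start <= t2$fx$region$end &
                   t2$blocks$ref_end >= t2$fx$region$start, ]
  manual <- unique(unlist(lapply(seq_len(nrow(hit)), function(i)
    t2$comp$feature_id[t2$comp$chromosome == hit$comp_chr[i] &
                       t2$comp$start <= hit$comp_end[i] &
                       t2$comp$end >= hit$comp_start[i]])))
  expect_setequal(ds$comparison$feature_id, manual)
})

test_that("lung replay: either-genome term search finds the eleven genes", {
  lg <- get_lung()
  mt <- run_term_filter(lg, "positive regulation of cell death", "GO", "either")
  refs <- ref_gene_ids(mt)
  expect_length(refs, 11)
  expect_setequal(refs, c("MYB", "CCN2", "MAP3K5", "HEBP2", "BCLAF1", "TIAM2",
                          "IL20RA", "LATS1", "FNDC1", "IGF2R", "PRKN"))
  prov <- mt[mt$genome == "reference", ]
  expect_equal(prov$provenance[prov$feature_id == "PRKN"], "via_ortholog")
  expect_equal(prov$provenance[prov$feature_id == "MYB"], "self")
  expect_equal(prov$provenance[prov$feature_id == "TIAM2"], "self")
})

test_that("lung replay: reference-genome scope drops the mouse-only match", {
  lg <- get_lung()
  mt <- run_term_filter(lg, "positive regulation of cell death", "GO",
                        "reference")
  refs <- ref_gene_ids(mt)
  expect_false("PRKN" %in% refs)
  expect_length(refs, 10)
  expect_true(all(c("MYB", "TIAM2") %in% refs))
})

test_that("an empty annotation set yields an empty match table", {
  lg <- get_lung()
  empty_ann <- structure(
    list(annotations = lg$ann$annotations[0, ],
         negative = lg$ann$negative[0, ], n_dropped = 0L),
    class = "annotation_set")
  q <- filter_query(filter_clause("term", "positive regulation of cell death",
                                  "GO"),
                    region = lg$fx$region)
  mt <- apply_filter(q, lg$ds, empty_ann, lg$onts, lg$orth)
  expect_equal(nrow(mt), 0)
})

test_that("AND matches are a subset of OR matches and scopes union to either", {
  lg <- get_lung()
  clauses <- list(filter_clause("term", "positive regulation of cell death",
                                "GO"),
                  filter_clause("symbol", "MYB"))
  mk <- function(comb, scope) {
    q <- filter_query(clauses, combinator = comb, scope = scope,
                      region = lg$fx$region)
    apply_filter(q, lg$ds, lg$ann, lg$onts, lg$orth)
  }
  and_ids <- unique(mk("AND", "either")$feature_id)
  or_ids <- unique(mk("OR", "either")$feature_id)
  expect_true(all(and_ids %in% or_ids))
  expect_setequal(and_ids, c("MYB", "Myb"))

  key <- function(mt) unique(paste(mt$genome, mt$feature_id, mt$matched_clause))
  either <- mk("OR", "either")
  expect_setequal(union(key(mk("OR", "reference")), key(mk("OR", "comparison"))),
                  key(either))
})

test_that("feature-type and symbol clauses work and the toggle is metadata-only", {
  t2 <- get_t2dm()
  q1 <- filter_query(filter_clause("feature_type", "QTL"),
                     scope = "reference", region = t2$fx$region)
  mt1 <- apply_filter(q1, t2$ds, t2$ann, t2$onts, t2$orth)
  expect_equal(ref_gene_ids(mt1), "T2dm2sa")

  q2 <- filter_query(filter_clause("feature_type", "QTL"),
                     scope = "reference", region = t2$fx$region,
                     exclude_nonmatching = TRUE)
  mt2 <- apply_filter(q2, t2$ds, t2$ann, t2$onts, t2$orth)
  expect_equal(as.data.frame(mt1), as.data.frame(mt2), ignore_attr = TRUE)
  expect_false(attr(mt1, "exclude_nonmatching"))
  expect_true(attr(mt2, "exclude_nonmatching"))

  expect_error(
    apply_filter(filter_query(filter_clause("term", "no such term", "MP"),
                              region = t2$fx$region),
                 t2$ds, t2$ann, t2$onts, t2$orth),
    "term not found")
})

test_that("match tables round trip through CSV, quoting as needed", {
  lg <- get_lung()
  mt <- run_term_filter(lg, "positive regulation of cell death", "GO", "either")
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_matches_csv(mt, tmp)
  back <- read_matches_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(mt), ignore_attr = TRUE)

  # empty table -> header only
  empty <- mt[0, ]
  class(empty) <- class(mt)
  export_matches_csv(empty, tmp)
  expect_equal(length(readLines(tmp)), 1)
  expect_equal(nrow(read_matches_csv(tmp)), 0)

  # a comma in a symbol gets quoted and survives
  odd <- as.data.frame(mt)[1, ]
  odd$symbol <- "WEIRD, GENE"
  class(odd) <- class(mt)
  export_matches_csv(odd, tmp)
  expect_true(any(grepl("\"WEIRD, GENE\"", readLines(tmp))))
  expect_equal(read_matches_csv(tmp)$symbol, "WEIRD, GENE")
})

test_that("reference feature search ranks exact symbols first and honours terms", {
  t2 <- get_t2dm()
  hits <- search_reference_features(t2$ref, t2$ann, t2$onts, "T2dm2sa")
  expect_equal(hits$feature_id[1], "T2dm2sa")
  expect_equal(hits$feature_type[1], "QTL")
  expect_equal(c(hits$start[1], hits$end[1]), c(29417935, 148533014))

  expect_equal(nrow(search_reference_features(t2$ref, t2$ann, t2$onts,
                                              "NOPE999")), 0)

  # term query equals composition with features_annotated_to
  byterm <- search_reference_features(t2$ref, t2$ann, t2$onts,
                                      "impaired glucose tolerance")
  manual <- intersect(
    features_annotated_to(t2$ann, t2$onts$MP, "MP:0005293",
                          taxon_id = t2$fx$ref_taxon),
    t2$ref$feature_id)
  expect_setequal(byterm$feature_id, manual)

  # prefix match, case-insensitive
  pre <- search_reference_features(t2$ref, t2$ann, t2$onts, "mdec")
  expect_equal(nrow(pre), 8)
})
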