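toy_obo <- function(lines) {
  tmp <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), tmp)
  tmp
}

test_that("OBO stanzas load with is_a and part_of edges retained", {
  path <- toy_obo(c(
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: middle", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: leaf",
    "relationship: part_of T:2 ! middle",
    "relationship: regulates T:1 ! root", "",
    "[Term]", "id: T:4", "name: gone", "is_obsolete: true",
    "is_a: T:1 ! root", ""))
  ont <- read_obo(path)
  expect_equal(nrow(ont$terms), 4)
  expect_true(ont$terms$obsolete[ont$terms$term_id == "T:4"])
  expect_equal(ont$edges$parent_id[ont$edges$term_id == "T:2"], "T:1")
  # part_of retained, regulates ignored, obsolete term contributes no edges
  e3 <- ont$edges[ont$edges$term_id == "T:3", ]
  expect_equal(e3$parent_id, "T:2")
  expect_equal(e3$relation, "part_of")
  expect_false("T:4" %in% ont$edges$term_id)
  # obsolete terms stay out of the closure
  expect_false("T:4" %in% descendant_closure(ont, "T:1"))
})

test_that("cycles among retained edges are reported", {
  path <- toy_obo(c(
    "[Term]", "id: C:1", "name: a", "is_a: C:2", "",
    "[Term]", "id: C:2", "name: b", "is_a: C:1", ""))
  expect_error(read_obo(path), "cycle")
})

test_that("closure is reflexive, transitive and matches reachability", {
  path <- toy_obo(c(
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: a", "is_a: T:1", "",
    "[Term]", "id: T:3", "name: b", "is_a: T:2", ""))
  ont <- read_obo(path)
  expect_equal(descendant_closure(ont, "T:3"), "T:3")
  expect_equal(descendant_closure(ont, "T:1"), c("T:1", "T:2", "T:3"))
  expect_error(descendant_closure(ont, "T:9"), "unknown term")

  dag <- read_obo(random_dag(200, edge_prob = 0.03, seed = 17))
  ids <- dag$terms$term_id
  for (t in sample(ids, 25)) {
    cl <- descendant_closure(dag, t)
    expect_equal(cl, igraph_closure(dag, t))
    expect_true(t %in% cl)
    # transitivity
    for (u in sample(cl, min(3, length(cl))))
      expect_true(all(descendant_closure(dag, u) %in% cl))
  }
})

test_that("GAF rows split into positive and NOT sets, unknown terms dropped", {
  path <- toy_obo(c(
    "[Term]", "id: G:1", "name: proc", "",
    "[Term]", "id: G:2", "name: old", "is_obsolete: true", ""))
  ont <- read_obo(path)
  gaf <- tempfile(fileext = ".gaf")
  mk <- function(id, term, qual = "") paste(
    c("DB", id, id, qual, term, "REF:1", "IEA", "", "P", "", "", "gene",
      "taxon:10090", "20200101", "DB", "", ""), collapse = "\t")
  writeLines(c("!gaf-version: 2.2",
               mk("g1", "G:1"), mk("g2", "G:1"),
               mk("g3", "G:1", "NOT"),
               mk("g4", "G:2"),       # obsolete -> dropped
               mk("g5", "G:9")),      # unknown -> dropped
             gaf)
  expect_warning(ann <- read_gaf(gaf, ont), "dropped 2")
  expect_equal(nrow(ann$annotations), 2)
  expect_equal(sort(ann$annotations$feature_id), c("g1", "g2"))
  expect_equal(ann$negative$feature_id, "g3")
  expect_equal(ann$n_dropped, 2L)
  expect_equal(ann$annotations$taxon_id, c(10090L, 10090L))

  writeLines(c("!header", "DB\tg1\tg1"), gaf)
  expect_error(read_gaf(gaf, ont), "line 2")
})

test_that("annotation retrieval follows closure and excludes NOT rows", {
  path <- toy_obo(c(
    "[Term]", "id: P:1", "name: parent", "",
    "[Term]", "id: P:2", "name: child", "is_a: P:1", ""))
  ont <- read_obo(path)
  gaf <- tempfile(fileext = ".gaf")
  mk <- function(id, term, qual = "") paste(
    c("DB", id, id, qual, term, "REF:1", "IEA", "", "P", "", "", "gene",
      "taxon:1", "20200101", "DB", "", ""), collapse = "\t")
  writeLines(c(mk("child_only", "P:2"), mk("not_only", "P:1", "NOT")), gaf)
  ann <- read_gaf(gaf, ont)
  expect_equal(features_annotated_to(ann, ont, "P:1"), "child_only")
  expect_equal(features_annotated_to(ann, ont, "P:2"), "child_only")
  expect_false("not_only" %in% features_annotated_to(ann, ont, "P:1"))
})

test_that("retrieval equals brute force and is anti-monotone on random DAGs", {
  dag <- read_obo(random_dag(60, edge_prob = 0.06, seed = 4))
  ids <- dag$terms$term_id
  set.seed(8)
  ann_df <- data.frame(
    feature_id = sprintf("g%03d", sample.int(40, 150, TRUE)),
    symbol = "x", term_id = sample(ids, 150, TRUE), qualifiers = "",
    evidence_code = "IEA", taxon_id = 1L, stringsAsFactors = FALSE)
  ann <- structure(list(annotations = ann_df,
                        negative = ann_df[0, ], n_dropped = 0L),
                   class = "annotation_set")
  for (t in sample(ids, 15)) {
    got <- features_annotated_to(ann, dag, t)
    expect_equal(got, bruteforce_annotated(ann, dag, t))
    # every ancestor of t retrieves a superset
    anc <- dag$edges$parent_id[dag$edges$term_id == t]
    for (a in anc)
      expect_true(all(got %in% features_annotated_to(ann, dag, a)))
  }
})

test_that("terms resolve by ID, case-insensitive name, and synonym", {
  path <- toy_obo(c(
    "[Term]", "id: S:1", "name: Increased Insulin",
    'synonym: "hyperinsulinemia" EXACT []', ""))
  ont <- read_obo(path)
  expect_equal(resolve_term(ont, "S:1"), "S:1")
  expect_equal(resolve_term(ont, "increased insulin"), "S:1")
  expect_equal(resolve_term(ont, "HYPERINSULINEMIA"), "S:1")
  expect_true(is.na(resolve_term(ont, "nope")))
})
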