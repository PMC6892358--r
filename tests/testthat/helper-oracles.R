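# Independent oracles used across the suite.  These deliberately use
# different implementation strategies from the package internals.

# Brute-force maximal-run scanner over an anchor table: for each start
# position, extend the run as far as the rules allow, emit it, and resume
# after its end.  Returns a data frame of runs (start index, end index,
# orientation) in scan order.
oracle_runs <- function(anchors, min_anchors = 1) {
  n <- nrow(anchors)
  if (n == 0) return(data.frame(from = integer(), to = integer(),
                                orientation = character()))
  runs <- list()
  s <- 1L
  while (s <= n) {
    e <- s
    dir <- 0L
    while (e < n) {
      d <- anchors$comp_ord[e + 1L] - anchors$comp_ord[e]
      if (abs(d) != 1) break
      if (anchors$ref_chr[e + 1L] != anchors$ref_chr[e]) break
      if (anchors$comp_chr[e + 1L] != anchors$comp_chr[e]) break
      if (dir != 0L && sign(d) != dir) break
      dir <- sign(d)
      e <- e + 1L
    }
    runs[[length(runs) + 1L]] <- data.frame(
      from = s, to = e,
      orientation = if (dir == 0L) "+" else if (dir > 0L) "+" else "-",
      stringsAsFactors = FALSE)
    s <- e + 1L
  }
  out <- do.call(rbind, runs)
  out[(out$to - out$from + 1L) >= min_anchors, , drop = FALSE]
}

# Blocks (span table) from oracle runs, for direct comparison with
# compute_blocks output.
oracle_blocks <- function(index, min_anchors = 2) {
  a <- index$anchors
  runs <- oracle_runs(a, min_anchors)
  if (!nrow(runs)) return(NULL)
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    seg <- a[runs$from[i]:runs$to[i], , drop = FALSE]
    data.frame(ref_chr = seg$ref_chr[1],
               ref_start = min(seg$ref_start), ref_end = max(seg$ref_end),
               comp_chr = seg$comp_chr[1],
               comp_start = min(seg$comp_start), comp_end = max(seg$comp_end),
               orientation = runs$orientation[i], stringsAsFactors = FALSE)
  }))
}

# Reachability oracle for descendant closure, via igraph: all nodes from
# which `term` can be reached along child->parent edges, i.e. the "in"
# neighbourhood of term in the child->parent digraph.
igraph_closure <- function(ontology, term) {
  g <- igraph::graph_from_data_frame(
    ontology$edges[, c("term_id", "parent_id")], directed = TRUE,
    vertices = ontology$terms$term_id)
  sort(names(igraph::subcomponent(g, term, mode = "in")))
}

# Brute-force double loop: features annotated to term or any descendant.
bruteforce_annotated <- function(annotations, ontology, term) {
  desc <- igraph_closure(ontology, term)
  ann <- annotations$annotations
  hits <- character()
  for (i in seq_len(nrow(ann)))
    for (t in desc)
      if (ann$term_id[i] == t) hits <- c(hits, ann$feature_id[i])
  sort(unique(hits))
}

random_permutation <- function(n) sample.int(n)

# A loaded lung fixture bundle shared across tests (built once per run).
lung_env <- new.env()
get_lung <- function() {
  if (is.null(lung_env$fx)) {
    fx <- make_usecase_fixture("lung")
    lung_env$fx <- fx
    lung_env$ref <- read_gff3(fx$ref_gff3, fx$ref_taxon)
    lung_env$comp <- read_gff3(fx$comp_gff3, fx$comp_taxon)
    lung_env$blocks <- read_block_file(fx$blocks)
    lung_env$onts <- list(GO = read_obo(fx$obo[["GO"]]))
    lung_env$ann <- read_gaf(fx$gaf[["GO"]], lung_env$onts$GO)
    lung_env$orth <- read_ortholog_pairs(fx$orthologs)
    lung_env$ds <- resolve_display_set(fx$region, lung_env$blocks,
                                       lung_env$ref, lung_env$comp)
  }
  as.list(lung_env)
}

t2dm_env <- new.env()
get_t2dm <- function() {
  if (is.null(t2dm_env$fx)) {
    fx <- make_usecase_fixture("t2dm")
    t2dm_env$fx <- fx
    t2dm_env$ref <- read_gff3(fx$ref_gff3, fx$ref_taxon)
    t2dm_env$comp <- read_gff3(fx$comp_gff3, fx$comp_taxon)
    t2dm_env$blocks <- read_block_file(fx$blocks)
    t2dm_env$onts <- list(MP = read_obo(fx$obo[["MP"]]),
                          DO = read_obo(fx$obo[["DO"]]))
    t2dm_env$ann <- combine_annotations(
      read_gaf(fx$gaf[["MP"]], t2dm_env$onts$MP),
      read_gaf(fx$gaf[["DO"]], t2dm_env$onts$DO))
    t2dm_env$orth <- read_ortholog_pairs(fx$orthologs)
    t2dm_env$ds <- resolve_display_set(fx$region, t2dm_env$blocks,
                                       t2dm_env$ref, t2dm_env$comp)
  }
  as.list(t2dm_env)
}

run_term_filter <- function(bundle, term, ontology, scope,
                            combinator = "OR") {
  q <- filter_query(filter_clause("term", term, ontology),
                    combinator = combinator, scope = scope,
                    region = bundle$fx$region)
  apply_filter(q, bundle$ds, bundle$ann, bundle$onts, bundle$orth)
}

ref_gene_ids <- function(mt) unique(mt$feature_id[mt$genome == "reference"])
comp_gene_ids <- function(mt) unique(mt$feature_id[mt$genome == "comparison"])
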