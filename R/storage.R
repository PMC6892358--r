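#' Load all inputs into a single-file embedded data store
#'
#' Runs the four loaders in order — (1) genome features and synteny
#' blocks, (2) ontologies, (3) annotations, (4) configuration — and writes
#' one self-contained store file holding relational tables plus load
#' provenance (source paths, row counts, timestamp).  Re-running on the
#' same inputs replaces the store; it never duplicates rows.  Annotations
#' citing genes absent from the feature tables are dropped and the drop
#' count recorded.
#'
#' @param db_path output store file (conventionally `.syndb`).
#' @param ref_gff3,comp_gff3 genome feature GFF3 paths.
#' @param ref_config,comp_config per-genome configuration files.
#' @param orthologs ortholog pair TSV.
#' @param blocks_file optional precomputed block file; when `NULL`, blocks
#'   are computed from the ortholog anchors.
#' @param obo_paths named character vector of OBO files (names are the
#'   ontology names referenced by annotations and filter clauses).
#' @param gaf_paths named character vector of GAF files; each name must be
#'   one of the ontology names, routing the file to its ontology.
#' @param min_anchors passed to [compute_blocks()] when computing blocks.
#' @return object of class `synteny_db`, invisibly written to `db_path`.
#' @export
etl_load <- function(db_path, ref_gff3, comp_gff3, ref_config, comp_config,
                     orthologs, blocks_file = NULL, obo_paths = character(),
                     gaf_paths = character(), min_anchors = 2) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_syn("loader '%s' failed: %s", name, conditionMessage(e)))
  }
  cfgs <- step("config", load_genome_config_pair(c(ref_config, comp_config)))
  ref_build <- cfgs$reference; comp_build <- cfgs$comparison

  ref_features <- step("features", read_gff3(ref_gff3, ref_build$taxon_id,
                       symbol_attribute = ref_build$symbol_attribute))
  comp_features <- step("features", read_gff3(comp_gff3, comp_build$taxon_id,
                        symbol_attribute = comp_build$symbol_attribute))
  pairs <- step("features", read_ortholog_pairs(orthologs))
  blocks <- step("blocks", if (is.null(blocks_file)) {
    idx <- index_anchors(ref_features, comp_features, pairs)
    compute_blocks(idx, min_anchors = min_anchors)
  } else read_block_file(blocks_file))

  ontologies <- step("ontologies",
                     stats::setNames(lapply(obo_paths, read_obo),
                                     names(obo_paths)))

  known_ids <- c(ref_features$feature_id, comp_features$feature_id)
  n_ann_dropped <- 0L
  ann_sets <- list()
  for (nm in names(gaf_paths)) {
    if (!nm %in% names(ontologies))
      stop_syn("loader 'annotations' failed: GAF '%s' names no loaded ontology", nm)
    s <- step("annotations", read_gaf(gaf_paths[[nm]], ontologies[[nm]]))
    unknown <- !(s$annotations$feature_id %in% known_ids)
    n_ann_dropped <- n_ann_dropped + sum(unknown)
    s$annotations <- s$annotations[!unknown, , drop = FALSE]
    ann_sets[[nm]] <- s
  }
  annotations <- if (length(ann_sets)) do.call(combine_annotations, ann_sets)
                 else read_gaf_empty()
  if (n_ann_dropped)
    message(sprintf("etl_load: dropped %d annotation(s) citing unknown features",
                    n_ann_dropped))

  db <- structure(list(
    ref_build = ref_build, comp_build = comp_build,
    ref_features = ref_features, comp_features = comp_features,
    orthologs = pairs, blocks = blocks, ontologies = ontologies,
    annotations = annotations,
    provenance = list(
      sources = list(ref_gff3 = ref_gff3, comp_gff3 = comp_gff3,
                     orthologs = orthologs, blocks_file = blocks_file,
                     obo = as.list(obo_paths), gaf = as.list(gaf_paths)),
      row_counts = c(ref_features = nrow(ref_features),
                     comp_features = nrow(comp_features),
                     orthologs = nrow(pairs), blocks = nrow(blocks),
                     ontology_terms = sum(vapply(ontologies, function(o)
                       nrow(o$terms), integer(1))),
                     annotations = nrow(annotations$annotations)),
      annotations_dropped = n_ann_dropped,
      loaded_at = format(Sys.time(), tz = "UTC"))),
    class = "synteny_db")
  saveRDS(db, db_path)
  invisible(db)
}

read_gaf_empty <- function() {
  empty <- data.frame(feature_id = character(), symbol = character(),
                      term_id = character(), qualifiers = character(),
                      evidence_code = character(), taxon_id = integer(),
                      stringsAsFactors = FALSE)
  structure(list(annotations = empty, negative = empty, n_dropped = 0L),
            class = "annotation_set")
}

#' Open an existing store file
#'
#' @param db_path path written by [etl_load()].
#' @return a `synteny_db` object.
#' @export
open_db <- function(db_path) {
  if (!file.exists(db_path)) stop_syn("store not found: %s", db_path)
  db <- readRDS(db_path)
  if (!inherits(db, "synteny_db")) stop_syn("not a syntenykit store: %s", db_path)
  db
}

#' @export
print.synteny_db <- function(x, ...) {
  cat("<synteny_db>\n")
  print(x$provenance$row_counts)
  invisible(x)
}

SCHEMA_VERSION <- "1.0"

endpoint_ok <- function(data) {
  list(schema_version = SCHEMA_VERSION, status = "ok", data = data)
}
endpoint_error <- function(code, msg) {
  list(schema_version = SCHEMA_VERSION, status = "error", code = code,
       message = msg)
}

#' Query a store through a named endpoint
#'
#' Read-only JSON-style query endpoints over a loaded store, mirroring the
#' library operations one-to-one:
#' \describe{
#'   \item{`features-by-region`}{params `genome` ("reference"/"comparison"),
#'     `chromosome`, `start`, `end` — features overlapping the interval.}
#'   \item{`blocks-by-chromosome`}{param `chromosome` — blocks on that
#'     reference chromosome, as in [genome_overview()].}
#'   \item{`term-search`}{param `q` — reference features matching a symbol
#'     or ontology term, as in [search_reference_features()].}
#'   \item{`filter`}{params `clauses` (list of criterion/value/ontology),
#'     `combinator`, `scope`, `chromosome`, `start`, `end` — a
#'     [apply_filter()] match table.}
#'   \item{`overview`}{no params — the full [genome_overview()].}
#' }
#' Bad parameters yield a structured error document with an HTTP-style
#' code instead of an R error.
#'
#' @param db a `synteny_db`.
#' @param endpoint endpoint name.
#' @param params named list of endpoint parameters.
#' @return a list document with `schema_version`, `status`, and `data`
#'   (or `code`/`message` on error).  Use [endpoint_json()] for the JSON
#'   serialization.
#' @export
query_endpoint <- function(db, endpoint, params = list()) {
  tryCatch({
    data <- switch(endpoint,
      "features-by-region" = {
        genome <- if (is.null(params$genome)) "reference" else params$genome
        feats <- if (genome == "comparison") db$comp_features else db$ref_features
        taxon <- if (genome == "comparison") db$comp_build$taxon_id
                 else db$ref_build$taxon_id
        reg <- region_selection(taxon, params$chromosome,
                                params$start, params$end)
        suppressWarnings(features_in_region(feats, reg))
      },
      "blocks-by-chromosome" = {
        ov <- genome_overview(db$blocks)
        g <- ov[[strip_chr(params$chromosome)]]
        if (is.null(g)) g <- genome_overview(empty_blocks())[["none"]]
        if (is.null(g)) list() else g
      },
      "term-search" = {
        search_reference_features(db$ref_features, db$annotations,
                                  db$ontologies, params$q)
      },
      "filter" = {
        clauses <- lapply(params$clauses, function(cl)
          filter_clause(cl$criterion, cl$value, cl$ontology))
        reg <- region_selection(db$ref_build$taxon_id, params$chromosome,
                                params$start, params$end)
        q <- filter_query(clauses,
                          combinator = if (is.null(params$combinator)) "OR"
                                       else params$combinator,
                          scope = if (is.null(params$scope)) "either"
                                  else params$scope,
                          region = reg)
        ds <- suppressWarnings(resolve_display_set(reg, db$blocks,
                                                   db$ref_features,
                                                   db$comp_features))
        as.data.frame(apply_filter(q, ds, db$annotations, db$ontologies,
                                   db$orthologs))
      },
      "overview" = genome_overview(db$blocks),
      stop_syn("unknown endpoint: %s", endpoint))
    endpoint_ok(data)
  }, error = function(e) endpoint_error(400L, conditionMessage(e)))
}

#' Serialize an endpoint document as JSON
#'
#' @param doc a [query_endpoint()] result (or any library result wrapped
#'   the same way).
#' @return a JSON string (class `json`).
#' @export
endpoint_json <- function(doc) {
  jsonlite::toJSON(doc, auto_unbox = TRUE, dataframe = "rows", digits = NA,
                   na = "null")
}
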