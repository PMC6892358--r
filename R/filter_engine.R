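#' Build a filter clause
#'
#' One search criterion of the feature display filter: a feature symbol,
#' a feature type, or an ontology annotation term.
#'
#' @param criterion `"symbol"`, `"feature_type"` or `"term"`.
#' @param value the queried text: a symbol (or prefix), a feature type, or
#'   a term ID/name/synonym.
#' @param ontology name of the ontology to search (required for `"term"`),
#'   matching a name in the `ontologies` list given to [apply_filter()].
#' @return object of class `filter_clause`.
#' @export
filter_clause <- function(criterion = c("symbol", "feature_type", "term"),
                          value, ontology = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "term" && is.null(ontology))
    stop_syn("a 'term' clause requires an ontology name")
  structure(list(criterion = criterion, value = as.character(value),
                 ontology = ontology), class = "filter_clause")
}

#' Build a filter query
#'
#' Clauses are combined with a single top-level Boolean operator and
#' evaluated against a genome scope: `"reference"` or `"comparison"`
#' evaluates the clauses against that genome's features/annotations only
#' (matches are still reported on both genomes through orthology);
#' `"either"` accepts a match in either genome.
#'
#' @param clauses list of [filter_clause()] objects (at least one).
#' @param combinator `"AND"` or `"OR"`.
#' @param scope `"reference"`, `"comparison"` or `"either"`.
#' @param region the displayed reference-genome region
#'   (a [region_selection()]).
#' @param exclude_nonmatching display flag carried through to the result
#'   metadata; it never changes which rows match.
#' @return object of class `filter_query`.
#' @export
filter_query <- function(clauses, combinator = c("OR", "AND"),
                         scope = c("either", "reference", "comparison"),
                         region, exclude_nonmatching = FALSE) {
  combinator <- match.arg(combinator)
  scope <- match.arg(scope)
  if (inherits(clauses, "filter_clause")) clauses <- list(clauses)
  if (!length(clauses)) stop_syn("a filter query needs at least one clause")
  stopifnot(all(vapply(clauses, inherits, logical(1), "filter_clause")),
            inherits(region, "region_selection"))
  structure(list(clauses = clauses, combinator = combinator, scope = scope,
                 region = region, exclude_nonmatching = exclude_nonmatching),
            class = "filter_query")
}

#' Resolve the displayed feature set for a region
#'
#' The reference side contains the reference-genome features overlapping
#' the region; the comparison side contains the comparison-genome features
#' overlapping the comparison span of any synteny block that overlaps the
#' region (the block detail view is block-driven, not a plain coordinate
#' window on the comparison genome).
#'
#' @param region reference-genome [region_selection()].
#' @param blocks `synteny_blocks` for the genome pair.
#' @param ref_features,comp_features per-genome feature data frames.
#' @return list with elements `reference` and `comparison` (feature data
#'   frames) and `blocks` (the blocks overlapping the region).  A region
#'   in a synteny gap yields an empty comparison side with a warning.
#' @export
resolve_display_set <- function(region, blocks, ref_features, comp_features) {
  stopifnot(inherits(region, "region_selection"))
  ref_in <- features_in_region(ref_features, region, "any_overlap")
  hit <- blocks$ref_chr == region$chromosome &
         blocks$ref_start <= region$end & blocks$ref_end >= region$start
  hit_blocks <- blocks[hit, , drop = FALSE]
  if (!nrow(hit_blocks)) {
    warn_syn("region chr%s:%s-%s overlaps no synteny block", region$chromosome,
             format(region$start, scientific = FALSE),
             format(region$end, scientific = FALSE))
    comp_in <- empty_features()
  } else {
    per_block <- lapply(seq_len(nrow(hit_blocks)), function(i) {
      suppressWarnings(features_in_region(
        comp_features,
        region_selection(hit_blocks$comp_taxon[i], hit_blocks$comp_chr[i],
                         hit_blocks$comp_start[i], hit_blocks$comp_end[i]),
        "any_overlap"))
    })
    comp_in <- unique(do.call(rbind, per_block))
    comp_in <- comp_in[feature_order(comp_in), , drop = FALSE]
    rownames(comp_in) <- NULL
  }
  list(reference = ref_in, comparison = comp_in, blocks = hit_blocks)
}

# IDs on one side of the display set satisfying a single clause directly.
# Returns list(ids, term_id): term_id is the resolved query term for term
# clauses, NA otherwise.
clause_self_matches <- function(clause, side_features, annotations, ontologies) {
  if (clause$criterion == "symbol") {
    v <- tolower(clause$value)
    sym <- tolower(side_features$symbol)
    hit <- sym == v | startsWith(sym, v)
    list(ids = side_features$feature_id[hit], term_id = NA_character_)
  } else if (clause$criterion == "feature_type") {
    hit <- tolower(side_features$feature_type) == tolower(clause$value)
    list(ids = side_features$feature_id[hit], term_id = NA_character_)
  } else {
    ont <- ontologies[[clause$ontology]]
    if (is.null(ont))
      stop_syn("unknown ontology '%s' in term clause", clause$ontology)
    tid <- resolve_term(ont, clause$value)
    if (is.na(tid))
      stop_syn("term not found in ontology %s: %s", clause$ontology,
               clause$value)
    taxon <- if (nrow(side_features)) side_features$taxon_id[1] else NULL
    ann_ids <- features_annotated_to(annotations, ont, tid, taxon_id = taxon)
    list(ids = intersect(side_features$feature_id, ann_ids), term_id = tid)
  }
}

#' Apply a display filter to a resolved display set
#'
#' Each clause is evaluated on the genome(s) selected by the query scope;
#' a feature matches with provenance `"self"` when its own symbol, type or
#' annotation satisfies the clause, and with provenance `"via_ortholog"`
#' when the clause is satisfied by one of its orthologs in the other
#' genome.  Under `scope = "reference"` (resp. `"comparison"`) clauses are
#' evaluated against that genome only, and matching features are reported
#' on both genomes through the ortholog relation, mirroring how both
#' tracks are highlighted in a synteny display.  Clause results are
#' combined with the query's Boolean combinator.
#'
#' @param query a [filter_query()].
#' @param display_set a [resolve_display_set()] result.
#' @param annotations an `annotation_set` covering both genomes.
#' @param ontologies named list of `ontology` objects (names referenced by
#'   term clauses).
#' @param ortholog_pairs data frame of `ref_id`, `comp_id` pairs.
#' @return object of class `match_table`: data frame with columns
#'   `feature_id`, `symbol`, `genome`, `chromosome`, `start`, `end`,
#'   `feature_type`, `matched_clause`, `provenance`, `term_id`, sorted by
#'   (genome, chromosome, start, feature_id), deduplicated on
#'   (feature_id, matched_clause).  The query's `exclude_nonmatching` flag
#'   is carried in attribute `"exclude_nonmatching"`.
#' @export
apply_filter <- function(query, display_set, annotations, ontologies,
                         ortholog_pairs) {
  stopifnot(inherits(query, "filter_query"))
  sides <- list(reference = display_set$reference,
                comparison = display_set$comparison)
  nclause <- length(query$clauses)

  # self-match sets per side x clause
  self <- lapply(sides, function(sf)
    lapply(query$clauses, clause_self_matches, side_features = sf,
           annotations = annotations, ontologies = ontologies))

  # ortholog partners restricted to the display set
  pairs <- ortholog_pairs[ortholog_pairs$ref_id %in% sides$reference$feature_id |
                          ortholog_pairs$comp_id %in% sides$comparison$feature_id, ,
                          drop = FALSE]
  partners_of <- function(ids, from) {
    if (from == "comparison")
      pairs$ref_id[pairs$comp_id %in% ids]
    else
      pairs$comp_id[pairs$ref_id %in% ids]
  }

  # matched[side][[k]]: data frame id + provenance for clause k on side
  matched <- list(reference = vector("list", nclause),
                  comparison = vector("list", nclause))
  for (k in seq_len(nclause)) {
    ref_self <- self$reference[[k]]$ids
    comp_self <- self$comparison[[k]]$ids
    prov_df <- function(ids, prov) data.frame(
      feature_id = ids, provenance = rep_len(prov, length(ids)),
      stringsAsFactors = FALSE)
    via_ref <- intersect(partners_of(comp_self, "comparison"),
                         sides$reference$feature_id)
    via_comp <- intersect(partners_of(ref_self, "reference"),
                          sides$comparison$feature_id)
    sets <- switch(query$scope,
      reference = list(
        reference = prov_df(ref_self, "self"),
        comparison = prov_df(via_comp, "via_ortholog")),
      comparison = list(
        reference = prov_df(via_ref, "via_ortholog"),
        comparison = prov_df(comp_self, "self")),
      either = list(
        reference = rbind(prov_df(ref_self, "self"),
                          prov_df(setdiff(via_ref, ref_self), "via_ortholog")),
        comparison = rbind(prov_df(comp_self, "self"),
                           prov_df(setdiff(via_comp, comp_self),
                                   "via_ortholog"))))
    matched$reference[[k]] <- sets$reference
    matched$comparison[[k]] <- sets$comparison
  }

  rows <- list()
  for (side in c("reference", "comparison")) {
    sf <- sides[[side]]
    per_clause <- matched[[side]]
    all_ids <- unique(unlist(lapply(per_clause, `[[`, "feature_id")))
    for (id in all_ids) {
      in_clause <- vapply(per_clause, function(m) id %in% m$feature_id,
                          logical(1))
      ok <- if (query$combinator == "AND") all(in_clause) else any(in_clause)
      if (!ok) next
      f <- sf[sf$feature_id == id, , drop = FALSE]
      for (k in which(in_clause)) {
        m <- per_clause[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = id, symbol = f$symbol, genome = side,
          chromosome = f$chromosome, start = f$start, end = f$end,
          feature_type = f$feature_type, matched_clause = k,
          provenance = m$provenance[m$feature_id == id][1],
          term_id = self[[side]][[k]]$term_id, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    feature_id = character(), symbol = character(), genome = character(),
    chromosome = character(), start = numeric(), end = numeric(),
    feature_type = character(), matched_clause = integer(),
    provenance = character(), term_id = character(), stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(match(out$genome, c("reference", "comparison")),
                   chromosome_rank(out$chromosome), out$start,
                   out$feature_id, out$matched_clause), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclude_nonmatching") <- query$exclude_nonmatching
  class(out) <- c("match_table", "data.frame")
  out
}

#' Export a match table as CSV
#'
#' Writes an RFC-4180-style CSV with a header row; fields containing
#' commas or quotes are quoted.  [read_matches_csv()] reproduces the table.
#'
#' @param match_table an [apply_filter()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_matches_csv <- function(match_table, path) {
  df <- as.data.frame(match_table)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an exported match table CSV
#'
#' @param path CSV written by [export_matches_csv()].
#' @return a `match_table` data frame.
#' @export
read_matches_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(feature_id = "character",
                                       symbol = "character",
                                       genome = "character",
                                       chromosome = "character",
                                       start = "numeric", end = "numeric",
                                       feature_type = "character",
                                       matched_clause = "integer",
                                       provenance = "character",
                                       term_id = "character"))
  df$term_id[!is.na(df$term_id) & df$term_id == ""] <- NA_character_
  class(df) <- c("match_table", "data.frame")
  df
}

#' Search reference-genome features by symbol or annotation term
#'
#' Symbol matching is case-insensitive; exact matches rank before prefix
#' matches.  If the query resolves to a term in any supplied ontology, the
#' features annotated to the term or its descendants are also returned.
#' Results are sorted by genomic position within each rank.
#'
#' @param features reference-genome feature data frame.
#' @param annotations an `annotation_set`.
#' @param ontologies named list of ontologies to try for term resolution.
#' @param query_text symbol (or prefix), term ID, term name or synonym.
#' @return matching rows of `features` (possibly empty).
#' @export
search_reference_features <- function(features, annotations, ontologies,
                                      query_text) {
  q <- tolower(trimws(query_text))
  sym <- tolower(features$symbol)
  exact <- sym == q
  prefix <- startsWith(sym, q) & !exact

  term_ids <- character()
  for (ont in ontologies) {
    tid <- resolve_term(ont, query_text)
    if (!is.na(tid)) {
      taxon <- if (nrow(features)) features$taxon_id[1] else NULL
      term_ids <- union(term_ids,
                        features_annotated_to(annotations, ont, tid,
                                              taxon_id = taxon))
    }
  }
  by_term <- features$feature_id %in% term_ids & !exact & !prefix

  pick <- function(sel) {
    out <- features[sel, , drop = FALSE]
    out[feature_order(out), , drop = FALSE]
  }
  out <- rbind(pick(exact), pick(prefix), pick(by_term))
  rownames(out) <- NULL
  out
}
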