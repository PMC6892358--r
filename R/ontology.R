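#' Read an OBO ontology
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas.  `is_a` and `relationship: part_of`
#' edges are retained (the edges along which annotation propagates);
#' other relationship types are ignored.  Obsolete terms are loaded but
#' excluded from closure, and carry no parent edges.  A cycle among the
#' retained edges is an error.
#'
#' @param path OBO file.
#' @return an object of class `ontology`: list with data frames `terms`
#'   (`term_id`, `name`, `namespace`, `obsolete`), `edges` (`term_id`,
#'   `parent_id`, `relation`) and `synonyms` (`term_id`, `synonym`).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_syn("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)

  stanza_starts <- grep("^\\[Term\\]\\s*$", lines)
  all_starts <- grep("^\\[", lines)
  terms <- list(); edges <- list(); syns <- list()
  for (s in stanza_starts) {
    nxt <- all_starts[all_starts > s]
    body <- lines[(s + 1):(if (length(nxt)) nxt[1] - 1 else length(lines))]
    body <- body[nzchar(trimws(body))]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), body, value = TRUE))
      if (length(v)) sub("\\s*!.*$", "", v) else character()
    }
    id <- get1("id")
    if (!length(id)) stop_syn("OBO parse error: [Term] stanza without id near line %d", s)
    id <- trimws(id[1])
    name <- get1("name"); namespace <- get1("namespace")
    obsolete <- any(grepl("^is_obsolete:\\s*true", body))
    terms[[length(terms) + 1L]] <- data.frame(
      term_id = id,
      name = if (length(name)) trimws(name[1]) else "",
      namespace = if (length(namespace)) trimws(namespace[1]) else "",
      obsolete = obsolete, stringsAsFactors = FALSE)
    # synonym: "text" SCOPE [...]
    syn_lines <- grep("^synonym:", body, value = TRUE)
    if (length(syn_lines)) {
      sm <- regmatches(syn_lines, regexec('^synonym:\\s*"([^"]*)"', syn_lines))
      sv <- vapply(sm, function(g) if (length(g) >= 2) g[2] else NA_character_,
                   character(1))
      sv <- sv[!is.na(sv)]
      if (length(sv))
        syns[[length(syns) + 1L]] <- data.frame(term_id = id, synonym = sv,
                                                stringsAsFactors = FALSE)
    }
    if (!obsolete) {
      isa <- trimws(get1("is_a"))
      rel <- grep("^relationship:\\s*part_of\\s", body, value = TRUE)
      po <- trimws(sub("\\s*!.*$", "",
                       sub("^relationship:\\s*part_of\\s+", "", rel)))
      if (length(isa))
        edges[[length(edges) + 1L]] <- data.frame(term_id = id, parent_id = isa,
                                                  relation = "is_a",
                                                  stringsAsFactors = FALSE)
      if (length(po))
        edges[[length(edges) + 1L]] <- data.frame(term_id = id, parent_id = po,
                                                  relation = "part_of",
                                                  stringsAsFactors = FALSE)
    }
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(term_id = character(), name = character(),
               namespace = character(), obsolete = logical(),
               stringsAsFactors = FALSE)
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(term_id = character(), parent_id = character(),
               relation = character(), stringsAsFactors = FALSE)
  syns <- if (length(syns)) do.call(rbind, syns) else
    data.frame(term_id = character(), synonym = character(),
               stringsAsFactors = FALSE)
  rownames(terms) <- rownames(edges) <- rownames(syns) <- NULL

  ont <- structure(list(terms = terms, edges = edges, synonyms = syns),
                   class = "ontology")
  cyc <- find_cycle(ont)
  if (!is.null(cyc))
    stop_syn("cycle in ontology %s among retained edges: %s", path,
             paste(cyc, collapse = " -> "))
  ont
}

# Kahn's algorithm; returns NULL if acyclic, else one cycle as a term-id path.
find_cycle <- function(ont) {
  e <- ont$edges
  e <- e[e$parent_id %in% ont$terms$term_id, , drop = FALSE]
  nodes <- ont$terms$term_id
  indeg <- table(factor(e$parent_id, levels = nodes))  # edges point child->parent
  children_of <- split(e$parent_id, e$term_id)
  deg <- as.integer(indeg)
  names(deg) <- nodes
  queue <- nodes[deg == 0]
  removed <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    for (p in children_of[[v]]) {
      deg[p] <- deg[p] - 1L
      if (deg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (removed == length(nodes)) return(NULL)
  # walk parent edges from a remaining node until a repeat
  left <- names(deg)[deg > 0]
  parent_of <- split(e$parent_id, e$term_id)
  v <- left[1]; path <- v
  repeat {
    ps <- intersect(parent_of[[v]], left)
    v <- ps[1]
    if (v %in% path) return(c(path[which(path == v):length(path)], v))
    path <- c(path, v)
  }
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Descendant closure of an ontology term
#'
#' Returns the term itself plus every term reachable downward through
#' `is_a`/`part_of` child edges, to any depth.  Annotation to any member of
#' the closure counts as annotation to the queried term (the true-path
#' rule), which is what makes searches by a general term retrieve genes
#' annotated only to its specializations.
#'
#' @param ontology an [read_obo()] result.
#' @param term_id a term identifier present in the ontology.
#' @return sorted character vector of term IDs.
#' @export
descendant_closure <- function(ontology, term_id) {
  if (!term_id %in% ontology$terms$term_id)
    stop_syn("unknown term: %s", term_id)
  kids_of <- split(ontology$edges$term_id, ontology$edges$parent_id)
  seen <- term_id
  frontier <- term_id
  while (length(frontier)) {
    nxt <- unique(unlist(kids_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Resolve a term by ID, name or synonym
#'
#' Matching on name/synonym is case-insensitive and exact; a term ID is
#' accepted directly.
#'
#' @param ontology an [read_obo()] result.
#' @param query term ID, term name or synonym.
#' @return the term ID, or `NA_character_` if no match.
#' @export
resolve_term <- function(ontology, query) {
  if (query %in% ontology$terms$term_id) return(query)
  q <- tolower(trimws(query))
  hit <- ontology$terms$term_id[tolower(ontology$terms$name) == q &
                                !ontology$terms$obsolete]
  if (length(hit)) return(sort(hit)[1])
  hit <- ontology$synonyms$term_id[tolower(ontology$synonyms$synonym) == q]
  if (length(hit)) return(sort(hit)[1])
  NA_character_
}

#' Read gene-term annotations from a GAF 2.x file
#'
#' Parses the 17-column Gene Association Format.  Rows whose qualifier
#' contains `NOT` are excluded from the positive annotation set and kept
#' in a separate negative table; rows citing terms unknown to (or obsolete
#' in) the supplied ontology are dropped with a warning count.  All
#' evidence codes are accepted, including IEA.
#'
#' @param path GAF file; `!` comment lines are ignored.
#' @param ontology ontology the term column refers to; used to validate
#'   terms.  MP and DO association files in the same 17-column layout are
#'   read by the same code path.
#' @return object of class `annotation_set`: list with data frames
#'   `annotations` (positive) and `negative`, both with columns
#'   `feature_id`, `symbol`, `term_id`, `qualifiers`, `evidence_code`,
#'   `taxon_id`, plus `n_dropped` (count of unknown/obsolete-term rows).
#' @export
read_gaf <- function(path, ontology) {
  if (!file.exists(path)) stop_syn("GAF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(!|\\s*$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(feature_id = character(), symbol = character(),
                      term_id = character(), qualifiers = character(),
                      evidence_code = character(), taxon_id = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lines))
    return(structure(list(annotations = empty, negative = empty,
                          n_dropped = 0L), class = "annotation_set"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty optional columns may be omitted by writers; require >= 15
  if (any(nf < 15 | nf > 17))
    stop_syn("GAF parse error at line %d: expected 17 tab-separated columns, found %d",
             lineno[which(nf < 15 | nf > 17)[1]], nf[which(nf < 15 | nf > 17)[1]])
  grab <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[k] else "", character(1))
  taxon <- as.integer(sub("^taxon:", "", sub("\\|.*$", "", grab(13))))
  ann <- data.frame(feature_id = grab(2), symbol = grab(3),
                    term_id = grab(5), qualifiers = grab(4),
                    evidence_code = grab(7), taxon_id = taxon,
                    stringsAsFactors = FALSE)
  known <- ontology$terms$term_id[!ontology$terms$obsolete]
  ok <- ann$term_id %in% known
  n_dropped <- sum(!ok)
  if (n_dropped)
    warn_syn("read_gaf: dropped %d row(s) citing unknown or obsolete terms",
             n_dropped)
  ann <- ann[ok, , drop = FALSE]
  is_not <- vapply(strsplit(ann$qualifiers, "|", fixed = TRUE),
                   function(q) "NOT" %in% q, logical(1))
  pos <- ann[!is_not, , drop = FALSE]
  neg <- ann[is_not, , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(annotations = pos, negative = neg, n_dropped = n_dropped),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d positive, %d NOT-qualified, %d dropped\n",
              nrow(x$annotations), nrow(x$negative), x$n_dropped))
  invisible(x)
}

#' Combine annotation sets
#'
#' @param ... `annotation_set` objects (e.g. one per genome or ontology).
#' @return a single `annotation_set`.
#' @export
combine_annotations <- function(...) {
  sets <- list(...)
  structure(list(
    annotations = do.call(rbind, lapply(sets, `[[`, "annotations")),
    negative = do.call(rbind, lapply(sets, `[[`, "negative")),
    n_dropped = sum(vapply(sets, `[[`, integer(1), "n_dropped"))),
    class = "annotation_set")
}

#' Features annotated to a term or any of its descendants
#'
#' @param annotations an `annotation_set` (NOT-qualified rows are never
#'   counted as matches).
#' @param ontology the ontology the term belongs to.
#' @param term_id term whose descendant closure defines the match set.
#' @param taxon_id optional taxon restriction.
#' @return sorted character vector of feature IDs.
#' @export
features_annotated_to <- function(annotations, ontology, term_id,
                                  taxon_id = NULL) {
  terms <- descendant_closure(ontology, term_id)
  ann <- annotations$annotations
  hit <- ann$term_id %in% terms
  if (!is.null(taxon_id)) hit <- hit & ann$taxon_id == taxon_id
  sort(unique(ann$feature_id[hit]))
}

#' Export NOT-qualified annotations as TSV
#'
#' @param annotations an `annotation_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_negative_annotations <- function(annotations, path) {
  utils::write.table(annotations$negative, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
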