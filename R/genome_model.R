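#' Construct a genome build description
#'
#' A genome build names the organism (NCBI taxon), the assembly, the ordered
#' chromosome set with lengths, and the role the genome plays in a synteny
#' comparison (reference or comparison).
#'
#' @param taxon_id positive integer NCBI taxon identifier (10090 mouse,
#'   9606 human).
#' @param build_name assembly name, e.g. `"GRCm38"`.
#' @param chromosomes data frame with columns `name` and `length` (bp), in
#'   display order.  Names are stored without any `"chr"` prefix.
#' @param role `"reference"` or `"comparison"`.
#' @param ontologies character vector of ontology names available for this
#'   genome (e.g. `c("GO", "MP")`).
#' @param symbol_attribute GFF3 column-9 attribute key that carries the
#'   feature symbol (default `"Name"`).
#' @return an object of class `genome_build`.
#' @export
genome_build <- function(taxon_id, build_name, chromosomes,
                         role = c("reference", "comparison"),
                         ontologies = character(),
                         symbol_attribute = "Name") {
  role <- match.arg(role)
  taxon_id <- as.integer(taxon_id)
  if (is.na(taxon_id) || taxon_id <= 0)
    stop_syn("taxon_id must be a positive integer")
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  if (!all(c("name", "length") %in% names(chromosomes)))
    stop_syn("chromosomes must have columns 'name' and 'length'")
  chromosomes$name <- strip_chr(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop_syn("duplicate chromosome name: %s",
             chromosomes$name[duplicated(chromosomes$name)][1])
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0))
    stop_syn("chromosome lengths must be positive")
  structure(list(taxon_id = taxon_id, build_name = as.character(build_name),
                 chromosomes = chromosomes, role = role,
                 ontologies = as.character(ontologies),
                 symbol_attribute = symbol_attribute),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s (taxon %d), role=%s, %d chromosomes\n",
              x$build_name, x$taxon_id, x$role, nrow(x$chromosomes)))
  invisible(x)
}

#' Load a per-genome configuration file
#'
#' The configuration (YAML or JSON) names the taxon, assembly, chromosome
#' list, the ontologies enabled for the genome, and the GFF3 attribute key
#' holding feature symbols.  Unknown keys produce a warning, not an error.
#'
#' @param path configuration file path.
#' @return a [genome_build()] object; its `ontologies` field lists the
#'   ontologies available for the genome.
#' @export
load_genome_config <- function(path) {
  if (!file.exists(path)) stop_syn("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("taxon_id", "build_name", "role", "chromosomes", "ontologies",
             "symbol_attribute")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warn_syn("ignoring unknown config key(s): %s", paste(extra, collapse = ", "))
  if (is.null(cfg$taxon_id))
    stop_syn("config error: missing taxon_id in %s", path)
  if (is.null(cfg$chromosomes) || length(cfg$chromosomes) == 0)
    stop_syn("config error: missing chromosomes in %s", path)
  chroms <- cfg$chromosomes
  if (!is.data.frame(chroms))
    chroms <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(name = as.character(ch$name), length = as.numeric(ch$length),
                 stringsAsFactors = FALSE)))
  genome_build(taxon_id = cfg$taxon_id,
               build_name = if (is.null(cfg$build_name)) "" else cfg$build_name,
               chromosomes = chroms,
               role = if (is.null(cfg$role)) "reference" else cfg$role,
               ontologies = if (is.null(cfg$ontologies)) character()
                            else unlist(cfg$ontologies),
               symbol_attribute = if (is.null(cfg$symbol_attribute)) "Name"
                                  else cfg$symbol_attribute)
}

#' Load a reference/comparison pair of genome configurations
#'
#' @param paths character vector of two config paths.
#' @return named list with elements `reference` and `comparison`.
#' @export
load_genome_config_pair <- function(paths) {
  builds <- lapply(paths, load_genome_config)
  roles <- vapply(builds, function(b) b$role, character(1))
  if (anyDuplicated(roles))
    stop_syn("duplicate role '%s' across configuration files",
             roles[duplicated(roles)][1])
  stats::setNames(builds, roles)
}

#' Read genome features from a GFF3 file
#'
#' Reads top-level features (one row each) from a GFF3 file, keeping the
#' 1-based inclusive coordinates unchanged.  The feature type is taken
#' verbatim from column 3; the stable ID from the `ID` attribute; the symbol
#' from the attribute named by `symbol_attribute` (default `Name`).  Rows
#' whose type is not in `feature_types` (when given) are skipped and the
#' skip count is reported on stderr.
#'
#' @param path GFF3 file.
#' @param taxon_id taxon the features belong to.
#' @param feature_types optional character vector of types to keep (matched
#'   against column 3); `NULL` keeps every row.
#' @param symbol_attribute column-9 attribute key carrying the symbol.
#' @return data frame of features with columns `feature_id`, `symbol`,
#'   `taxon_id`, `chromosome`, `start`, `end`, `strand`, `feature_type`.
#' @export
read_gff3 <- function(path, taxon_id, feature_types = NULL,
                      symbol_attribute = "Name") {
  if (!file.exists(path)) stop_syn("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|\\s*$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_features())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop_syn("GFF3 parse error at line %d: expected 9 tab-separated columns, found %d",
             lineno[which(nf != 9)[1]], nf[which(nf != 9)[1]])
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)

  type <- m[, 3]
  skipped <- 0L
  sel <- rep(TRUE, nrow(m))
  if (!is.null(feature_types)) {
    sel <- type %in% feature_types
    skipped <- sum(!sel)
  }
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  if (skipped > 0)
    message(sprintf("read_gff3: parsed %d rows, skipped %d rows of unselected types",
                    nrow(m), skipped))

  start <- suppressWarnings(as.numeric(m[, 4]))
  end <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_syn("GFF3 parse error at line %d: non-numeric coordinates", lineno[bad[1]])
  inv <- which(start > end)
  if (length(inv))
    stop_syn("GFF3 validation error at line %d: start (%s) > end (%s)",
             lineno[inv[1]], format(start[inv[1]], scientific = FALSE),
             format(end[inv[1]], scientific = FALSE))

  attr_field <- m[, 9]
  get_attr <- function(attrs, key) {
    pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
    mm <- regmatches(attrs, regexec(pat, attrs))
    vapply(mm, function(g) if (length(g) >= 3) g[3] else NA_character_,
           character(1))
  }
  ids <- get_attr(attr_field, "ID")
  if (anyNA(ids))
    stop_syn("GFF3 parse error at line %d: missing ID attribute",
             lineno[which(is.na(ids))[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_syn("duplicate feature ID in %s: %s", path, dup[1])
  sym <- get_attr(attr_field, symbol_attribute)
  sym[is.na(sym)] <- ids[is.na(sym)]

  data.frame(feature_id = ids, symbol = sym,
             taxon_id = as.integer(taxon_id),
             chromosome = strip_chr(m[, 1]),
             start = start, end = end, strand = m[, 7],
             feature_type = type, stringsAsFactors = FALSE)
}

#' Write genome features to a GFF3 file
#'
#' Inverse of [read_gff3()]: emits one 9-column row per feature with `ID`
#' and `Name` attributes, so that write-then-read reproduces the feature
#' set exactly.
#'
#' @param features feature data frame as returned by [read_gff3()].
#' @param path output path.
#' @param source value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "syntenykit") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%s\t%s\t.\t%s\t.\tID=%s;Name=%s",
                     features$chromosome, source, features$feature_type,
                     format(features$start, scientific = FALSE, trim = TRUE),
                     format(features$end, scientific = FALSE, trim = TRUE),
                     ifelse(features$strand %in% c("+", "-"), features$strand, "."),
                     features$feature_id, features$symbol))
  writeLines(lines, path)
  invisible(path)
}

#' Define a genomic region selection
#'
#' @param taxon_id genome the region lives on.
#' @param chromosome chromosome name (a `"chr"` prefix is stripped).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return an object of class `region_selection`.
#' @export
region_selection <- function(taxon_id, chromosome, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end)
    stop_syn("invalid region: start (%s) must be <= end (%s)", start, end)
  if (start < 1) stop_syn("invalid region: start must be >= 1")
  structure(list(taxon_id = as.integer(taxon_id),
                 chromosome = strip_chr(chromosome),
                 start = start, end = end),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("<region> taxon %d chr%s:%s-%s\n", x$taxon_id, x$chromosome,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE)))
  invisible(x)
}

#' Select features overlapping or contained in a region
#'
#' Coordinates are 1-based inclusive, so a feature ending exactly at the
#' region start (or starting at the region end) overlaps it.
#'
#' @param features feature data frame.
#' @param region a [region_selection()].
#' @param overlap_mode `"any_overlap"` (default) keeps features with
#'   `start <= region end` and `end >= region start`; `"contained"`
#'   requires the feature to lie entirely inside the region.
#' @return the matching rows, sorted by (chromosome, start, end,
#'   feature_id).  An absent chromosome yields an empty result with a
#'   warning.
#' @export
features_in_region <- function(features, region,
                               overlap_mode = c("any_overlap", "contained")) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(inherits(region, "region_selection"))
  on_chr <- features$chromosome == region$chromosome &
            features$taxon_id == region$taxon_id
  if (!any(on_chr)) {
    warn_syn("no features on taxon %d chromosome %s",
             region$taxon_id, region$chromosome)
    return(empty_features())
  }
  hit <- if (overlap_mode == "any_overlap") {
    on_chr & features$start <= region$end & features$end >= region$start
  } else {
    on_chr & features$start >= region$start & features$end <= region$end
  }
  out <- features[hit, , drop = FALSE]
  out <- out[feature_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
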