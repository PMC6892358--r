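#' Read ortholog gene pairs
#'
#' Orthology between the two genomes is a binary relation of gene pairs,
#' supplied as a two-column tab-separated file (reference feature ID,
#' comparison feature ID).  `#` comment lines are ignored.  The relation
#' may contain one-to-many entries; [index_anchors()] reduces it to
#' one-to-one.
#'
#' @param path two-column TSV.
#' @return data frame with columns `ref_id`, `comp_id`.
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stop_syn("ortholog file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|\\s*$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(ref_id = character(), comp_id = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2))
    stop_syn("ortholog parse error at line %d: expected 2 columns, found %d",
             lineno[which(nf != 2)[1]], nf[which(nf != 2)[1]])
  m <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  unique(data.frame(ref_id = m[, 1], comp_id = m[, 2],
                    stringsAsFactors = FALSE))
}

#' Number ortholog anchors along both genomes
#'
#' Reduces the ortholog relation to one-to-one, then sorts each genome's
#' surviving anchored genes by chromosome and start position and numbers
#' them starting at 1.  Only genes that participate in the surviving
#' relation receive an ordinal, so unanchored genes never interrupt a run.
#'
#' @param ref_features,comp_features feature data frames (see [read_gff3()]).
#' @param pairs data frame of `ref_id`, `comp_id` ortholog pairs.
#' @param multi_policy how to resolve one-to-many entries:
#'   `"drop_ambiguous"` (default) removes every pair whose reference or
#'   comparison gene occurs in more than one pair;
#'   `"keep_first_by_position"` keeps, scanning pairs in genome order, the
#'   first pair for each gene not already committed, yielding an injective
#'   relation biased to upstream partners.
#' @return an object of class `anchor_index`: list with per-genome ordinal
#'   tables (`ref`, `comp`) and the joined anchor table `anchors` holding
#'   feature IDs, coordinates and ordinals for both genomes, in reference
#'   ordinal order.
#' @export
index_anchors <- function(ref_features, comp_features, pairs,
                          multi_policy = c("drop_ambiguous",
                                           "keep_first_by_position")) {
  multi_policy <- match.arg(multi_policy)
  pairs <- unique(pairs[, c("ref_id", "comp_id")])

  unknown_ref <- setdiff(pairs$ref_id, ref_features$feature_id)
  unknown_comp <- setdiff(pairs$comp_id, comp_features$feature_id)
  if (length(unknown_ref) || length(unknown_comp))
    stop_syn("ortholog pairs reference unknown feature ID(s): %s",
             paste(utils::head(c(unknown_ref, unknown_comp), 10),
                   collapse = ", "))

  if (multi_policy == "drop_ambiguous") {
    ok <- !(pairs$ref_id %in% pairs$ref_id[duplicated(pairs$ref_id)]) &
          !(pairs$comp_id %in% pairs$comp_id[duplicated(pairs$comp_id)])
    pairs <- pairs[ok, , drop = FALSE]
  } else {
    # order candidate pairs by genomic position of both partners, then
    # greedily commit pairs whose genes are both still free
    rpos <- match(pairs$ref_id, ref_features$feature_id)
    cpos <- match(pairs$comp_id, comp_features$feature_id)
    ord <- order(chromosome_rank(ref_features$chromosome[rpos]),
                 ref_features$start[rpos],
                 chromosome_rank(comp_features$chromosome[cpos]),
                 comp_features$start[cpos],
                 pairs$ref_id, pairs$comp_id)
    pairs <- pairs[ord, , drop = FALSE]
    seen_r <- character(); seen_c <- character()
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs$ref_id[i] %in% seen_r) && !(pairs$comp_id[i] %in% seen_c)) {
        keep[i] <- TRUE
        seen_r <- c(seen_r, pairs$ref_id[i])
        seen_c <- c(seen_c, pairs$comp_id[i])
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  }

  number_side <- function(features, ids) {
    f <- features[features$feature_id %in% ids, , drop = FALSE]
    f <- f[order(chromosome_rank(f$chromosome), f$start, f$end, f$feature_id), ,
           drop = FALSE]
    f$ordinal <- seq_len(nrow(f))
    rownames(f) <- NULL
    f
  }
  ref_idx <- number_side(ref_features, pairs$ref_id)
  comp_idx <- number_side(comp_features, pairs$comp_id)

  ri <- match(pairs$ref_id, ref_idx$feature_id)
  ci <- match(pairs$comp_id, comp_idx$feature_id)
  anchors <- data.frame(
    ref_id = pairs$ref_id, comp_id = pairs$comp_id,
    ref_ord = ref_idx$ordinal[ri], comp_ord = comp_idx$ordinal[ci],
    ref_chr = ref_idx$chromosome[ri], comp_chr = comp_idx$chromosome[ci],
    ref_start = ref_idx$start[ri], ref_end = ref_idx$end[ri],
    comp_start = comp_idx$start[ci], comp_end = comp_idx$end[ci],
    stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$ref_ord), , drop = FALSE]
  rownames(anchors) <- NULL

  structure(list(ref = ref_idx, comp = comp_idx, anchors = anchors,
                 ref_taxon = if (nrow(ref_idx)) ref_idx$taxon_id[1] else NA_integer_,
                 comp_taxon = if (nrow(comp_idx)) comp_idx$taxon_id[1] else NA_integer_),
            class = "anchor_index")
}

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("<anchor_index> %d one-to-one anchors (ref taxon %s, comp taxon %s)\n",
              nrow(x$anchors), x$ref_taxon, x$comp_taxon))
  invisible(x)
}

#' Build an anchor index directly from a comparison-ordinal permutation
#'
#' Convenience constructor for studying the block scanner: anchor `i` on
#' the reference maps to comparison ordinal `perm[i]`.  Gene spans are
#' synthetic (ordinal * 1000, length 500).  Chromosome assignments may be
#' supplied per reference anchor and per comparison ordinal.
#'
#' @param perm integer permutation of `1:n` (the comparison ordinals met
#'   while scanning the reference).
#' @param ref_chr character vector of reference chromosomes per anchor
#'   (default all `"1"`).
#' @param comp_chr character vector of comparison chromosomes per
#'   comparison ordinal (default all `"1"`).
#' @param ref_taxon,comp_taxon taxon IDs.
#' @return an `anchor_index` object.
#' @export
anchor_index_from_permutation <- function(perm, ref_chr = NULL,
                                          comp_chr = NULL,
                                          ref_taxon = 90001L,
                                          comp_taxon = 90002L) {
  n <- length(perm)
  stopifnot(setequal(perm, seq_len(n)))
  if (is.null(ref_chr)) ref_chr <- rep("1", n)
  if (is.null(comp_chr)) comp_chr <- rep("1", n)
  span <- function(ord) cbind(start = ord * 1000, end = ord * 1000 + 499)
  rs <- span(seq_len(n)); cs <- span(seq_len(n))
  ref <- data.frame(feature_id = sprintf("R%04d", seq_len(n)),
                    symbol = sprintf("R%04d", seq_len(n)),
                    taxon_id = ref_taxon, chromosome = ref_chr,
                    start = rs[, 1], end = rs[, 2], strand = "+",
                    feature_type = "gene", ordinal = seq_len(n),
                    stringsAsFactors = FALSE)
  comp <- data.frame(feature_id = sprintf("C%04d", seq_len(n)),
                     symbol = sprintf("C%04d", seq_len(n)),
                     taxon_id = comp_taxon, chromosome = comp_chr,
                     start = cs[, 1], end = cs[, 2], strand = "+",
                     feature_type = "gene", ordinal = seq_len(n),
                     stringsAsFactors = FALSE)
  anchors <- data.frame(
    ref_id = ref$feature_id, comp_id = comp$feature_id[perm],
    ref_ord = seq_len(n), comp_ord = perm,
    ref_chr = ref_chr, comp_chr = comp_chr[perm],
    ref_start = ref$start, ref_end = ref$end,
    comp_start = comp$start[perm], comp_end = comp$end[perm],
    stringsAsFactors = FALSE)
  structure(list(ref = ref, comp = comp, anchors = anchors,
                 ref_taxon = ref_taxon, comp_taxon = comp_taxon),
            class = "anchor_index")
}

#' Compute framed, collinear synteny blocks
#'
#' Scans the reference genome's anchors in ordinal order and notes the
#' succession of comparison-genome ordinals.  Each maximal run of
#' sequential comparison indices — ascending or descending — on unchanged
#' chromosomes in both genomes defines one synteny block.  Orientation is
#' `"+"` when the comparison indices increase along the run and `"-"`
#' (an inversion) when they decrease.  Block boundaries are the outer
#' limits of the member genes in each genome.
#'
#' @param index an [index_anchors()] result.
#' @param min_anchors minimum anchors per emitted block (default 2;
#'   single-anchor runs have no defined direction and are emitted with
#'   orientation `"+"` only when `min_anchors = 1`).
#' @param mode `"consecutive"` (default) requires the comparison ordinal to
#'   change by exactly +1 or -1 between adjacent anchors;
#'   `"monotonic"` relaxes this to any change of constant sign, for
#'   exploratory use.
#' @param id_tag tag used in block identifiers `SynBlock:<tag>:<n>`;
#'   defaults to the concatenated taxon shorthands (e.g. `"mmhs"`).
#' @return object of class `synteny_blocks`: a data frame with columns
#'   `ref_chr`, `ref_taxon`, `ref_start`, `ref_end`, `comp_chr`,
#'   `comp_taxon`, `comp_start`, `comp_end`, `orientation`, `block_id`,
#'   plus a list column `anchors` holding each block's member anchor table.
#' @export
compute_blocks <- function(index, min_anchors = 2,
                           mode = c("consecutive", "monotonic"),
                           id_tag = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "anchor_index"), min_anchors >= 1)
  a <- index$anchors
  if (is.null(id_tag))
    id_tag <- paste0(taxon_tag(index$ref_taxon), taxon_tag(index$comp_taxon))
  if (nrow(a) == 0) return(empty_blocks())

  n <- nrow(a)
  run_id <- integer(n)
  run_id[1] <- 1L
  dir <- 0L  # direction of the current run: 0 undecided, +1, -1
  for (i in seq_len(n)[-1]) {
    d <- a$comp_ord[i] - a$comp_ord[i - 1L]
    same_chr <- a$ref_chr[i] == a$ref_chr[i - 1L] &&
                a$comp_chr[i] == a$comp_chr[i - 1L]
    step_ok <- if (mode == "consecutive") abs(d) == 1 else d != 0
    extends <- same_chr && step_ok && (dir == 0L || sign(d) == dir)
    if (extends) {
      run_id[i] <- run_id[i - 1L]
      dir <- sign(d)
    } else {
      run_id[i] <- run_id[i - 1L] + 1L
      dir <- 0L
    }
  }

  runs <- split(seq_len(n), run_id)
  blocks <- lapply(runs, function(ix) {
    if (length(ix) < min_anchors) return(NULL)
    b <- a[ix, , drop = FALSE]
    orientation <- if (length(ix) >= 2) {
      if (b$comp_ord[2] > b$comp_ord[1]) "+" else "-"
    } else "+"
    data.frame(ref_chr = b$ref_chr[1], ref_taxon = index$ref_taxon,
               ref_start = min(b$ref_start), ref_end = max(b$ref_end),
               comp_chr = b$comp_chr[1], comp_taxon = index$comp_taxon,
               comp_start = min(b$comp_start), comp_end = max(b$comp_end),
               orientation = orientation, block_id = NA_character_,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(blocks, is.null, logical(1))
  if (!any(keep)) return(empty_blocks())
  out <- do.call(rbind, blocks[keep])
  out$block_id <- sprintf("SynBlock:%s:%d", id_tag, seq_len(nrow(out)))
  out$anchors <- I(lapply(runs[keep], function(ix) {
    b <- a[ix, c("ref_id", "comp_id", "ref_start", "ref_end",
                 "comp_start", "comp_end"), drop = FALSE]
    rownames(b) <- NULL
    b
  }))
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

empty_blocks <- function() {
  out <- data.frame(ref_chr = character(), ref_taxon = integer(),
                    ref_start = numeric(), ref_end = numeric(),
                    comp_chr = character(), comp_taxon = integer(),
                    comp_start = numeric(), comp_end = numeric(),
                    orientation = character(), block_id = character(),
                    stringsAsFactors = FALSE)
  out$anchors <- I(list())
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d block(s)\n", nrow(x)))
  if (nrow(x))
    print(as.data.frame(x)[, setdiff(names(x), "anchors")], ...)
  invisible(x)
}

#' Write synteny blocks in the ten-column block format
#'
#' One tab-delimited line per block: reference chromosome, taxon ID, start
#' and end; comparison chromosome, taxon ID, start and end; orientation
#' (`+`/`-`); and `ID=<identifier>`, where identifiers must be unique
#' across the file.  Member anchors are not serialized — the format carries
#' spans only.
#'
#' @param blocks a `synteny_blocks` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_block_file <- function(blocks, path) {
  if (anyDuplicated(blocks$block_id))
    stop_syn("duplicate block ID: %s",
             blocks$block_id[duplicated(blocks$block_id)][1])
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%d\t%s\t%s\t%s\tID=%s",
                   blocks$ref_chr, blocks$ref_taxon,
                   fmt(blocks$ref_start), fmt(blocks$ref_end),
                   blocks$comp_chr, blocks$comp_taxon,
                   fmt(blocks$comp_start), fmt(blocks$comp_end),
                   blocks$orientation, blocks$block_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a ten-column synteny block file
#'
#' Accepts both bare identifiers and `ID=`-prefixed identifiers in the
#' final column.  Blocks read from a file carry no anchors.
#'
#' @param path block file.
#' @return a `synteny_blocks` object.
#' @export
read_block_file <- function(path) {
  if (!file.exists(path)) stop_syn("block file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|\\s*$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10))
    stop_syn("block file parse error at line %d: expected 10 tab-separated columns, found %d",
             lineno[which(nf != 10)[1]], nf[which(nf != 10)[1]])
  m <- matrix(unlist(fields), ncol = 10, byrow = TRUE)
  orientation <- m[, 9]
  bad_or <- which(!orientation %in% c("+", "-"))
  if (length(bad_or))
    stop_syn("block file error at line %d: orientation must be '+' or '-', found '%s'",
             lineno[bad_or[1]], orientation[bad_or[1]])
  ids <- sub("^ID=", "", m[, 10])
  if (anyDuplicated(ids))
    stop_syn("duplicate block ID in %s: %s", path, ids[duplicated(ids)][1])
  out <- data.frame(ref_chr = strip_chr(m[, 1]), ref_taxon = as.integer(m[, 2]),
                    ref_start = as.numeric(m[, 3]), ref_end = as.numeric(m[, 4]),
                    comp_chr = strip_chr(m[, 5]), comp_taxon = as.integer(m[, 6]),
                    comp_start = as.numeric(m[, 7]), comp_end = as.numeric(m[, 8]),
                    orientation = orientation, block_id = ids,
                    stringsAsFactors = FALSE)
  if (any(out$ref_start > out$ref_end) || any(out$comp_start > out$comp_end))
    stop_syn("block file error: start > end in %s", path)
  out$anchors <- I(rep(list(NULL), nrow(out)))
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Compute synteny blocks end to end from files
#'
#' Convenience pipeline: read both genomes' GFF3, the ortholog pairs,
#' index anchors and compute blocks.
#'
#' @inheritParams compute_blocks
#' @param ref_gff3,comp_gff3 GFF3 paths.
#' @param orthologs ortholog pair TSV path.
#' @param ref_taxon,comp_taxon taxon IDs for the two genomes.
#' @param multi_policy see [index_anchors()].
#' @return a `synteny_blocks` object.
#' @export
blocks_from_files <- function(ref_gff3, comp_gff3, orthologs,
                              ref_taxon, comp_taxon, min_anchors = 2,
                              mode = "consecutive",
                              multi_policy = "drop_ambiguous", id_tag = NULL) {
  ref <- read_gff3(ref_gff3, ref_taxon)
  comp <- read_gff3(comp_gff3, comp_taxon)
  pairs <- read_ortholog_pairs(orthologs)
  idx <- index_anchors(ref, comp, pairs, multi_policy = multi_policy)
  compute_blocks(idx, min_anchors = min_anchors, mode = mode, id_tag = id_tag)
}
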