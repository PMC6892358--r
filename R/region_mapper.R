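#' Map a reference interval to comparison-genome intervals
#'
#' For every synteny block overlapping the region, reports the overlapped
#' reference sub-span and the corresponding comparison interval at two
#' granularities: the block's full comparison span, and the anchor-trimmed
#' span (the hull of comparison coordinates of anchors whose reference
#' gene overlaps the region).  No within-block base-pair interpolation is
#' performed — the block model defines none.
#'
#' @param region reference-genome [region_selection()].
#' @param blocks `synteny_blocks`; anchor trimming needs computed blocks
#'   (file-loaded blocks carry no anchors and get `NA` trimmed spans).
#' @return data frame of mapped intervals ordered by reference position:
#'   `block_id`, `ref_chr`, `ref_start`, `ref_end` (sub-span clipped to
#'   the region), `comp_chr`, `comp_start`, `comp_end` (full block span),
#'   `trim_comp_start`, `trim_comp_end` (anchor hull), `orientation`.
#' @export
map_region <- function(region, blocks) {
  stopifnot(inherits(region, "region_selection"))
  hit <- blocks$ref_chr == region$chromosome &
         blocks$ref_start <= region$end & blocks$ref_end >= region$start
  b <- blocks[hit, , drop = FALSE]
  if (!nrow(b))
    return(data.frame(block_id = character(), ref_chr = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      comp_chr = character(), comp_start = numeric(),
                      comp_end = numeric(), trim_comp_start = numeric(),
                      trim_comp_end = numeric(), orientation = character(),
                      stringsAsFactors = FALSE))
  trim <- t(vapply(seq_len(nrow(b)), function(i) {
    anc <- b$anchors[[i]]
    if (is.null(anc) || !nrow(anc)) return(c(NA_real_, NA_real_))
    in_reg <- anc$ref_start <= region$end & anc$ref_end >= region$start
    if (!any(in_reg)) return(c(NA_real_, NA_real_))
    c(min(anc$comp_start[in_reg]), max(anc$comp_end[in_reg]))
  }, numeric(2)))
  out <- data.frame(block_id = b$block_id, ref_chr = b$ref_chr,
                    ref_start = pmax(b$ref_start, region$start),
                    ref_end = pmin(b$ref_end, region$end),
                    comp_chr = b$comp_chr, comp_start = b$comp_start,
                    comp_end = b$comp_end,
                    trim_comp_start = trim[, 1], trim_comp_end = trim[, 2],
                    orientation = b$orientation, stringsAsFactors = FALSE)
  out <- out[order(out$ref_start, out$ref_end, out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-level synteny overview
#'
#' The complete block listing grouped by reference chromosome — the data
#' behind a circos-style genome view with the reference genome as the
#' outer ring and the comparison genome as the inner ring.
#'
#' @param blocks `synteny_blocks`.
#' @return named list (one element per reference chromosome, in canonical
#'   chromosome order) of data frames with columns `ref_start`, `ref_end`,
#'   `comp_chr`, `comp_start`, `comp_end`, `orientation`, `block_id`.
#'   JSON-serializable as-is.
#' @export
genome_overview <- function(blocks) {
  df <- as.data.frame(blocks)[, c("ref_chr", "ref_start", "ref_end",
                                  "comp_chr", "comp_start", "comp_end",
                                  "orientation", "block_id")]
  df <- df[order(chromosome_rank(df$ref_chr), df$ref_start, df$ref_end,
                 df$block_id), , drop = FALSE]
  chrs <- unique(df$ref_chr)
  out <- lapply(chrs, function(ch) {
    g <- df[df$ref_chr == ch, setdiff(names(df), "ref_chr"), drop = FALSE]
    rownames(g) <- NULL
    g
  })
  stats::setNames(out, chrs)
}

#' Anchor guidelines for a block
#'
#' One (reference gene span, comparison gene span) pair per member anchor,
#' in reference order — the data behind the guideline lines connecting
#' anchor features across the two tracks of a block detail display.
#'
#' @param blocks `synteny_blocks`.
#' @param block_id which block.
#' @return data frame with columns `ref_id`, `comp_id`, `ref_start`,
#'   `ref_end`, `comp_start`, `comp_end`.  A file-loaded block carries no
#'   anchors: empty result with a warning.
#' @export
anchor_guidelines <- function(blocks, block_id) {
  i <- match(block_id, blocks$block_id)
  if (is.na(i)) stop_syn("unknown block ID: %s", block_id)
  anc <- blocks$anchors[[i]]
  if (is.null(anc) || !nrow(anc)) {
    warn_syn("block %s carries no anchors (loaded from file?)", block_id)
    return(data.frame(ref_id = character(), comp_id = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      comp_start = numeric(), comp_end = numeric(),
                      stringsAsFactors = FALSE))
  }
  anc <- anc[order(anc$ref_start, anc$ref_end, anc$ref_id), , drop = FALSE]
  rownames(anc) <- NULL
  anc
}
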