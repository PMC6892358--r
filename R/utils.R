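# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic chromosome ordering: numeric chromosomes ascending, then
# X, Y, MT, then anything else lexicographically.  Used wherever features
# must be sorted "by chromosome and start position".
chromosome_rank <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(chr))
  special <- match(toupper(chr), c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(num), num,
          ifelse(!is.na(special), 1e6 + special, NA))
  # non-standard names sort after everything, alphabetically
  other <- is.na(rank)
  if (any(other)) {
    lex <- match(chr[other], sort(unique(chr[other])))
    rank[other] <- 2e6 + lex
  }
  rank
}

# Order features by (chromosome, start, end, feature_id) — the package's
# canonical total order on features.
feature_order <- function(df) {
  order(chromosome_rank(df$chromosome), df$start, df$end, df$feature_id)
}

# Strip a leading "chr" prefix from chromosome names.
strip_chr <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Short taxon tags used in default block identifiers (e.g. mouse+human ->
# "mmhs", matching identifiers like SynBlock:mmhs:1).
taxon_tag <- function(taxon_id) {
  known <- c(`10090` = "mm", `9606` = "hs", `10116` = "rn", `7955` = "dr",
             `9031` = "gg", `7227` = "dm", `6239` = "ce")
  tag <- known[as.character(taxon_id)]
  ifelse(is.na(tag), paste0("t", taxon_id), tag)
}

stop_syn <- function(fmt, ..., class = "syntenykit_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

warn_syn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

empty_features <- function() {
  data.frame(feature_id = character(), symbol = character(),
             taxon_id = integer(), chromosome = character(),
             start = numeric(), end = numeric(), strand = character(),
             feature_type = character(), stringsAsFactors = FALSE)
}
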