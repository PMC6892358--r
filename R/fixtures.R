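#' Simulate a genome pair with planted rearrangements
#'
#' Genome A carries `n_genes` in order along its chromosomes; genome B is
#' A transformed by a randomly drawn plan of segment inversions and
#' inter-chromosomal translocations whose breakpoints always fall between
#' genes.  Gene spans are non-overlapping with fixed spacing, so the true
#' synteny blocks are known by construction: each maximal stretch of genome
#' B carrying consecutive A-indices on a single chromosome of both genomes
#' is one block, ascending stretches oriented `"+"` and descending (i.e.
#' inverted) stretches `"-"`.  The same seed reproduces byte-identical
#' files.
#'
#' @param n_genes total genes per genome (>= 2).
#' @param n_inversions,n_translocations rearrangement counts (>= 0);
#'   translocations need at least two chromosomes.
#' @param seed RNG seed for the plan.
#' @param n_chromosomes chromosomes per genome (genes split evenly).
#' @param dir output directory (created if needed).
#' @param min_anchors anchors needed for an expected block (default 2,
#'   matching [compute_blocks()]).
#' @return list with file paths (`ref_gff3`, `comp_gff3`, `orthologs`,
#'   `expected_blocks_file`), the expected `synteny_blocks` object
#'   (`expected_blocks`), the taxon IDs and the applied `plan`.
#' @export
simulate_genome_pair <- function(n_genes, n_inversions = 0,
                                 n_translocations = 0, seed = 1,
                                 n_chromosomes = 1,
                                 dir = tempfile("synpair"),
                                 min_anchors = 2) {
  stopifnot(n_genes >= 2, n_inversions >= 0, n_translocations >= 0,
            n_chromosomes >= 1)
  if (n_translocations > 0 && n_chromosomes < 2)
    stop_syn("translocations need at least two chromosomes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_taxon <- 90001L; comp_taxon <- 90002L

  # genome A layout: chromosomes "1".."k", genes in index order
  chr_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
  a_layout <- split(seq_len(n_genes), chr_of)   # chrom name -> a-indices

  spacing <- 20000; glen <- 10000
  coords <- function(pos) {
    start <- (pos - 1) * spacing + 1
    cbind(start = start, end = start + glen - 1)
  }

  # genome B starts as A and is rearranged; breakpoints between genes
  b_layout <- a_layout
  plan <- list()
  with_seed(seed, {
    for (r in seq_len(n_inversions)) {
      elig <- names(b_layout)[lengths(b_layout) >= 2]
      ch <- sample(elig, 1)
      n <- length(b_layout[[ch]])
      ij <- sort(sample.int(n, 2))
      b_layout[[ch]][ij[1]:ij[2]] <- rev(b_layout[[ch]][ij[1]:ij[2]])
      plan[[length(plan) + 1L]] <- list(op = "inversion", chrom = ch,
                                        from = ij[1], to = ij[2])
    }
    for (r in seq_len(n_translocations)) {
      elig <- names(b_layout)[lengths(b_layout) >= 1]
      if (length(elig) < 1 || length(b_layout) < 2)
        stop_syn("no placeable translocation left")
      src <- sample(elig, 1)
      n <- length(b_layout[[src]])
      ij <- sort(sample.int(n, min(2, n)))
      if (length(ij) == 1) ij <- c(ij, ij)
      seg <- b_layout[[src]][ij[1]:ij[2]]
      b_layout[[src]] <- b_layout[[src]][-(ij[1]:ij[2])]
      dst <- sample(setdiff(names(b_layout), src), 1)
      at <- sample.int(length(b_layout[[dst]]) + 1L, 1) - 1L
      b_layout[[dst]] <- append(b_layout[[dst]], seg, after = at)
      plan[[length(plan) + 1L]] <- list(op = "translocation", from_chrom = src,
                                        from = ij[1], to = ij[2],
                                        to_chrom = dst, at = at)
    }
  })

  layout_features <- function(layout, taxon, id_prefix, sym_prefix) {
    rows <- lapply(names(layout), function(ch) {
      idx <- layout[[ch]]
      if (!length(idx)) return(NULL)
      cc <- coords(seq_along(idx))
      data.frame(feature_id = sprintf("%s%04d", id_prefix, idx),
                 symbol = sprintf("%s%04d", sym_prefix, idx),
                 taxon_id = taxon, chromosome = ch,
                 start = cc[, "start"], end = cc[, "end"],
                 strand = "+", feature_type = "protein coding gene",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  ref_features <- layout_features(a_layout, ref_taxon, "GA", "geneA")
  comp_features <- layout_features(b_layout, comp_taxon, "GB", "geneB")

  ref_gff3 <- file.path(dir, "ref.gff3")
  comp_gff3 <- file.path(dir, "comp.gff3")
  write_gff3(ref_features, ref_gff3)
  write_gff3(comp_features, comp_gff3)
  orth_path <- file.path(dir, "orthologs.tsv")
  writeLines(c("# ref_id\tcomp_id",
               sprintf("GA%04d\tGB%04d", seq_len(n_genes), seq_len(n_genes))),
             orth_path)

  # expected blocks, derived from the constructed layout: scan each B
  # chromosome for maximal stretches of consecutive A-indices on one A
  # chromosome
  groups <- list()
  for (ch in names(b_layout)) {
    v <- b_layout[[ch]]
    if (!length(v)) next
    brk <- c(TRUE, abs(diff(v)) != 1 | chr_of[v[-length(v)]] != chr_of[v[-1]])
    gid <- cumsum(brk)
    for (g in split(seq_along(v), gid)) {
      groups[[length(groups) + 1L]] <- list(b_chrom = ch, a_idx = v[g],
                                            b_pos = g)
    }
  }
  exp_rows <- lapply(groups, function(g) {
    if (length(g$a_idx) < min_anchors) return(NULL)
    aseg <- ref_features[match(sprintf("GA%04d", g$a_idx),
                               ref_features$feature_id), ]
    bseg <- comp_features[match(sprintf("GB%04d", g$a_idx),
                                comp_features$feature_id), ]
    data.frame(ref_chr = aseg$chromosome[1], ref_taxon = ref_taxon,
               ref_start = min(aseg$start), ref_end = max(aseg$end),
               comp_chr = g$b_chrom, comp_taxon = comp_taxon,
               comp_start = min(bseg$start), comp_end = max(bseg$end),
               orientation = if (length(g$a_idx) >= 2 &&
                                 g$a_idx[2] < g$a_idx[1]) "-" else "+",
               block_id = NA_character_, stringsAsFactors = FALSE)
  })
  exp_rows <- exp_rows[!vapply(exp_rows, is.null, logical(1))]
  expected <- if (length(exp_rows)) do.call(rbind, exp_rows) else
    as.data.frame(empty_blocks())[, 1:10]
  expected <- expected[order(chromosome_rank(expected$ref_chr),
                             expected$ref_start, expected$ref_end), ,
                       drop = FALSE]
  if (nrow(expected))
    expected$block_id <- sprintf("SynBlock:%s%s:%d", taxon_tag(ref_taxon),
                                 taxon_tag(comp_taxon), seq_len(nrow(expected)))
  expected$anchors <- I(rep(list(NULL), nrow(expected)))
  rownames(expected) <- NULL
  class(expected) <- c("synteny_blocks", "data.frame")

  exp_path <- file.path(dir, "expected_blocks.tsv")
  write_block_file(expected, exp_path)

  list(ref_gff3 = ref_gff3, comp_gff3 = comp_gff3, orthologs = orth_path,
       expected_blocks_file = exp_path, expected_blocks = expected,
       ref_taxon = ref_taxon, comp_taxon = comp_taxon, plan = plan,
       dir = dir)
}

gaf_line <- function(id, symbol, term, taxon, qualifier = "",
                     evidence = "IEA", aspect = "P", type = "gene") {
  paste(c("SYN", id, symbol, qualifier, term, "SYN:0001", evidence, "",
          aspect, symbol, "", type, paste0("taxon:", taxon), "20200101",
          "SYN", "", ""), collapse = "\t")
}

obo_term <- function(id, name, parents = character(), obsolete = FALSE,
                     synonyms = character(), namespace = "") {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    if (nzchar(namespace)) paste0("namespace: ", namespace),
    sprintf("is_a: %s ! parent", parents),
    sprintf('synonym: "%s" EXACT []', synonyms),
    if (obsolete) "is_obsolete: true", "")
}

#' Build a self-contained use-case fixture bundle
#'
#' Two bundles reproduce, on synthetic data, the worked candidate-gene
#' searches the package targets:
#' \describe{
#'   \item{`lung`}{Reference = human.  A lung-cancer susceptibility
#'     linkage interval on chromosome 6 (130,300,000-161,000,000 bp)
#'     contains eleven genes annotated to the GO term
#'     "positive regulation of cell death" in at least one genome —
#'     PRKN in mouse only, MYB and TIAM2 in human only, eight in both —
#'     plus unannotated decoy genes inside the interval and annotated
#'     genes outside it.  The syntenic mouse segment is inverted.}
#'   \item{`t2dm`}{Reference = mouse.  Chromosome 2 carries the
#'     T2dm2sa QTL (29,417,935-148,533,014 bp, GRCm38) as a QTL feature,
#'     mouse genes annotated to Mammalian Phenotype terms (impaired
#'     glucose tolerance; increased circulating insulin level; increased
#'     body mass index), and human orthologs in two syntenic blocks, three
#'     of which (GPD2, NEUROD1, MAPK8IP1) are annotated to the Disease
#'     Ontology term "type 2 diabetes mellitus".}
#' }
#' Every queried term has one parent and one child in its toy ontology so
#' that descendant closure is exercised; gene coordinates other than the
#' QTL span and the chromosome-6 interval are synthetic.
#'
#' @param case `"lung"` or `"t2dm"`.
#' @param dir output directory.
#' @return list of file paths (`ref_gff3`, `comp_gff3`, `orthologs`,
#'   `blocks`, per-ontology `obo`/`gaf`, `ref_config`, `comp_config`),
#'   the query `region`, and the taxon IDs.
#' @export
make_usecase_fixture <- function(case = c("lung", "t2dm"),
                                 dir = tempfile("usecase")) {
  case <- match.arg(case)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (case == "lung") make_lung_fixture(dir) else make_t2dm_fixture(dir)
}

write_config <- function(path, taxon, build, role, chroms, onts, key = "Name") {
  yaml::write_yaml(list(
    taxon_id = taxon, build_name = build, role = role,
    chromosomes = lapply(seq_len(nrow(chroms)), function(i)
      list(name = chroms$name[i], length = chroms$length[i])),
    ontologies = as.list(onts), symbol_attribute = key), path)
  path
}

make_lung_fixture <- function(dir) {
  go_terms <- c(
    obo_term("GO:0008150", "biological_process", namespace = "biological_process"),
    obo_term("GO:0010941", "regulation of cell death", "GO:0008150"),
    obo_term("GO:0010942", "positive regulation of cell death", "GO:0010941"),
    obo_term("GO:0043068", "positive regulation of programmed cell death",
             "GO:0010942"),
    obo_term("GO:0043069", "negative regulation of programmed cell death",
             "GO:0010941"),
    obo_term("GO:0999999", "withdrawn process", obsolete = TRUE))
  obo_path <- file.path(dir, "go.obo")
  writeLines(c("format-version: 1.2", "", go_terms), obo_path)

  targets <- c("MYB", "CCN2", "MAP3K5", "HEBP2", "BCLAF1", "TIAM2",
               "IL20RA", "LATS1", "FNDC1", "IGF2R", "PRKN")
  decoys <- sprintf("LCDEC%02d", 1:10)
  outside <- sprintf("LCOUT%02d", 1:5)

  # human chr6: outside genes at 100-110 Mb, then targets/decoys
  # interleaved across the 130.3-161 Mb interval
  region_syms <- character(0)
  for (i in 1:10) region_syms <- c(region_syms, targets[i], decoys[i])
  region_syms <- c(region_syms, targets[11])
  hum_syms <- c(outside, region_syms)
  hum_start <- c(100e6 + (0:4) * 2e6,
                 130.4e6 + (seq_along(region_syms) - 1) * 1.4e6)
  hum <- data.frame(feature_id = hum_syms, symbol = hum_syms,
                    taxon_id = 9606L, chromosome = "6",
                    start = hum_start, end = hum_start + 99999,
                    strand = "+", feature_type = "protein coding gene",
                    stringsAsFactors = FALSE)

  mouse_case <- function(s) paste0(substr(s, 1, 1),
                                   tolower(substr(s, 2, nchar(s))))
  # mouse: outside-gene orthologs ascending on chr 17; region orthologs
  # on chr 10 in reversed order (an inverted syntenic segment)
  m17_syms <- mouse_case(outside)
  m10_syms <- mouse_case(rev(region_syms))
  mouse <- rbind(
    data.frame(feature_id = m10_syms, symbol = m10_syms, taxon_id = 10090L,
               chromosome = "10",
               start = 3e6 + (seq_along(m10_syms) - 1) * 3e5,
               end = 3e6 + (seq_along(m10_syms) - 1) * 3e5 + 49999,
               strand = "+", feature_type = "protein coding gene",
               stringsAsFactors = FALSE),
    data.frame(feature_id = m17_syms, symbol = m17_syms, taxon_id = 10090L,
               chromosome = "17",
               start = 5e6 + (seq_along(m17_syms) - 1) * 3e5,
               end = 5e6 + (seq_along(m17_syms) - 1) * 3e5 + 49999,
               strand = "+", feature_type = "protein coding gene",
               stringsAsFactors = FALSE))

  ref_gff3 <- file.path(dir, "human.gff3")
  comp_gff3 <- file.path(dir, "mouse.gff3")
  write_gff3(hum, ref_gff3)
  write_gff3(mouse, comp_gff3)

  orth_path <- file.path(dir, "orthologs.tsv")
  writeLines(sprintf("%s\t%s", hum$symbol, mouse_case(hum$symbol)), orth_path)

  blocks <- blocks_from_files(ref_gff3, comp_gff3, orth_path,
                              ref_taxon = 9606, comp_taxon = 10090)
  blocks_path <- file.path(dir, "blocks.tsv")
  write_block_file(blocks, blocks_path)

  both <- c("CCN2", "MAP3K5", "HEBP2", "BCLAF1", "IL20RA", "LATS1", "FNDC1")
  gaf <- c("!gaf-version: 2.2",
           # eight genes annotated in both genomes (IGF2R via the child term)
           vapply(both, function(s) gaf_line(s, s, "GO:0010942", 9606),
                  character(1)),
           vapply(both, function(s) gaf_line(mouse_case(s), mouse_case(s),
                                             "GO:0010942", 10090),
                  character(1)),
           gaf_line("IGF2R", "IGF2R", "GO:0043068", 9606),
           gaf_line("Igf2r", "Igf2r", "GO:0043068", 10090),
           # human-only and mouse-only annotations
           gaf_line("MYB", "MYB", "GO:0010942", 9606),
           gaf_line("TIAM2", "TIAM2", "GO:0010942", 9606),
           gaf_line("Prkn", "Prkn", "GO:0010942", 10090),
           # annotated genes outside the interval
           vapply(outside, function(s) gaf_line(s, s, "GO:0010942", 9606),
                  character(1)),
           # decoys: sibling-term annotations and one NOT row
           gaf_line("LCDEC01", "LCDEC01", "GO:0043069", 9606),
           gaf_line("LCDEC02", "LCDEC02", "GO:0043069", 9606),
           gaf_line("LCDEC03", "LCDEC03", "GO:0010942", 9606,
                    qualifier = "NOT|involved_in"))
  gaf_path <- file.path(dir, "go.gaf")
  writeLines(gaf, gaf_path)

  ref_config <- write_config(file.path(dir, "human.yaml"), 9606, "GRCh38",
                             "reference",
                             data.frame(name = c("6", "2"),
                                        length = c(170805979, 242193529)),
                             "GO")
  comp_config <- write_config(file.path(dir, "mouse.yaml"), 10090, "GRCm38",
                              "comparison",
                              data.frame(name = c("10", "17"),
                                         length = c(130694993, 94987271)),
                              "GO")

  list(case = "lung", ref_gff3 = ref_gff3, comp_gff3 = comp_gff3,
       orthologs = orth_path, blocks = blocks_path,
       obo = c(GO = obo_path), gaf = c(GO = gaf_path),
       ref_config = ref_config, comp_config = comp_config,
       region = region_selection(9606, "6", 130300000, 161000000),
       ref_taxon = 9606L, comp_taxon = 10090L,
       term = "positive regulation of cell death", ontology = "GO")
}

make_t2dm_fixture <- function(dir) {
  mp_terms <- c(
    obo_term("MP:0000001", "mammalian phenotype"),
    obo_term("MP:0005376", "homeostasis/metabolism phenotype", "MP:0000001"),
    obo_term("MP:0005293", "impaired glucose tolerance", "MP:0005376"),
    obo_term("MP:0011110", "severely impaired glucose tolerance", "MP:0005293"),
    obo_term("MP:0001560", "increased circulating insulin level", "MP:0005376",
             synonyms = "hyperinsulinemia"),
    obo_term("MP:0011111", "chronically increased circulating insulin level",
             "MP:0001560"),
    obo_term("MP:0010025", "increased body mass index", "MP:0005376"),
    obo_term("MP:0011112", "markedly increased body mass index", "MP:0010025"))
  do_terms <- c(
    obo_term("DOID:4", "disease"),
    obo_term("DOID:9351", "diabetes mellitus", "DOID:4"),
    obo_term("DOID:9352", "type 2 diabetes mellitus", "DOID:9351",
             synonyms = "T2DM"),
    obo_term("DOID:0110742", "type 2 diabetes mellitus 1", "DOID:9352"))
  mp_obo <- file.path(dir, "mp.obo")
  do_obo <- file.path(dir, "do.obo")
  writeLines(c("format-version: 1.2", "", mp_terms), mp_obo)
  writeLines(c("format-version: 1.2", "", do_terms), do_obo)

  igt <- c("Pkn3", "Lcn2", "Dpm2", "Zbtb43", "Bbs5", "Commd9", "Hipk3",
           "Pax6", "Hdc", "Ap4e1", "Chgb", "Pcsk2")
  insulin <- c("Lcn2", "Slc2a8", "Dpp4", "Bdnf", "Hdc", "Snap25", "Pcsk2")
  do_mouse <- c("Gpd2", "Neurod1", "Mapk8ip1")
  decoys <- sprintf("Mdec%02d", 1:8)
  outside <- sprintf("Mout%02d", 1:3)

  qtl_start <- 29417935; qtl_end <- 148533014
  in_qtl <- unique(c(igt, insulin, do_mouse, decoys))
  mouse_syms <- c(outside, in_qtl)
  mouse_start <- c(10e6 + (seq_along(outside) - 1) * 2e6,
                   qtl_start + 2e6 + (seq_along(in_qtl) - 1) * 3e6)
  stopifnot(max(mouse_start) + 99999 < qtl_end)
  mouse <- data.frame(feature_id = mouse_syms, symbol = mouse_syms,
                      taxon_id = 10090L, chromosome = "2",
                      start = mouse_start, end = mouse_start + 99999,
                      strand = "+", feature_type = "protein coding gene",
                      stringsAsFactors = FALSE)
  qtl <- data.frame(feature_id = "T2dm2sa", symbol = "T2dm2sa",
                    taxon_id = 10090L, chromosome = "2",
                    start = qtl_start, end = qtl_end, strand = ".",
                    feature_type = "QTL", stringsAsFactors = FALSE)
  mouse_all <- rbind(mouse, qtl)

  # human orthologs: outside genes -> chr 20 (ascending); first half of the
  # QTL genes -> chr 2 (ascending), second half -> chr 11 (inverted).
  # Gpd2/Neurod1 sort into the first half, Mapk8ip1 into the second.
  half1 <- in_qtl[seq_len(ceiling(length(in_qtl) / 2))]
  half2 <- setdiff(in_qtl, half1)
  if (!all(c("Gpd2", "Neurod1") %in% half1) || !"Mapk8ip1" %in% half2) {
    half1 <- unique(c(setdiff(half1, "Mapk8ip1"), "Gpd2", "Neurod1"))
    half2 <- setdiff(in_qtl, half1)
  }
  # keep mouse order within halves
  half1 <- in_qtl[in_qtl %in% half1]; half2 <- in_qtl[in_qtl %in% half2]
  hchr2 <- toupper(half1)
  hchr11 <- toupper(rev(half2))
  hchr20 <- toupper(outside)
  mkh <- function(syms, chrom, base) data.frame(
    feature_id = syms, symbol = syms, taxon_id = 9606L, chromosome = chrom,
    start = base + (seq_along(syms) - 1) * 2e6,
    end = base + (seq_along(syms) - 1) * 2e6 + 99999,
    strand = "+", feature_type = "protein coding gene",
    stringsAsFactors = FALSE)
  human <- rbind(mkh(hchr2, "2", 150e6), mkh(hchr11, "11", 40e6),
                 mkh(hchr20, "20", 30e6),
                 data.frame(feature_id = "DODECOY1", symbol = "DODECOY1",
                            taxon_id = 9606L, chromosome = "5", start = 1e6,
                            end = 1099999, strand = "+",
                            feature_type = "protein coding gene",
                            stringsAsFactors = FALSE))

  ref_gff3 <- file.path(dir, "mouse.gff3")
  comp_gff3 <- file.path(dir, "human.gff3")
  write_gff3(mouse_all, ref_gff3)
  write_gff3(human, comp_gff3)

  orth_path <- file.path(dir, "orthologs.tsv")
  writeLines(sprintf("%s\t%s", mouse_syms, toupper(mouse_syms)), orth_path)

  blocks <- blocks_from_files(ref_gff3, comp_gff3, orth_path,
                              ref_taxon = 10090, comp_taxon = 9606)
  blocks_path <- file.path(dir, "blocks.tsv")
  write_block_file(blocks, blocks_path)

  mp_gaf <- c("!gaf-version: 2.2",
              vapply(setdiff(igt, "Pcsk2"), function(s)
                gaf_line(s, s, "MP:0005293", 10090), character(1)),
              gaf_line("Pcsk2", "Pcsk2", "MP:0011110", 10090),
              vapply(insulin, function(s)
                gaf_line(s, s, "MP:0001560", 10090), character(1)),
              gaf_line("Snap25", "Snap25", "MP:0010025", 10090),
              vapply(outside, function(s)
                gaf_line(s, s, "MP:0005293", 10090), character(1)))
  do_gaf <- c("!gaf-version: 2.2",
              gaf_line("GPD2", "GPD2", "DOID:9352", 9606),
              gaf_line("NEUROD1", "NEUROD1", "DOID:0110742", 9606),
              gaf_line("MAPK8IP1", "MAPK8IP1", "DOID:9352", 9606),
              gaf_line("DODECOY1", "DODECOY1", "DOID:9352", 9606))
  mp_gaf_path <- file.path(dir, "mp.gaf")
  do_gaf_path <- file.path(dir, "do.gaf")
  writeLines(mp_gaf, mp_gaf_path)
  writeLines(do_gaf, do_gaf_path)

  ref_config <- write_config(file.path(dir, "mouse.yaml"), 10090, "GRCm38",
                             "reference",
                             data.frame(name = "2", length = 182113224),
                             c("MP", "DO"))
  comp_config <- write_config(file.path(dir, "human.yaml"), 9606, "GRCh38",
                              "comparison",
                              data.frame(name = c("2", "11", "20", "5"),
                                         length = c(242193529, 135086622,
                                                    64444167, 181538259)),
                              "DO")

  list(case = "t2dm", ref_gff3 = ref_gff3, comp_gff3 = comp_gff3,
       orthologs = orth_path, blocks = blocks_path,
       obo = c(MP = mp_obo, DO = do_obo),
       gaf = c(MP = mp_gaf_path, DO = do_gaf_path),
       ref_config = ref_config, comp_config = comp_config,
       region = region_selection(10090, "2", qtl_start, qtl_end),
       ref_taxon = 10090L, comp_taxon = 9606L)
}

#' Generate a random acyclic ontology in OBO format
#'
#' Terms are created in topological order and each term may draw parent
#' edges only toward earlier terms, so the output is acyclic by
#' construction and deterministic per seed.
#'
#' @param n_terms number of terms (>= 1).
#' @param edge_prob probability of a parent edge from each term to each
#'   earlier term (capped at 3 parents per term).
#' @param seed RNG seed.
#' @param path output OBO path.
#' @return `path`, invisibly; the file parses with [read_obo()].
#' @export
random_dag <- function(n_terms, edge_prob = 0.02, seed = 1,
                       path = tempfile(fileext = ".obo")) {
  stopifnot(n_terms >= 1)
  ids <- sprintf("RND:%07d", seq_len(n_terms))
  stanzas <- with_seed(seed, {
    lapply(seq_len(n_terms), function(i) {
      parents <- character()
      if (i > 1) {
        cand <- which(stats::runif(i - 1) < edge_prob)
        if (length(cand) > 3) cand <- sort(sample(cand, 3))
        parents <- ids[cand]
      }
      obo_term(ids[i], paste("random term", i), parents)
    })
  })
  writeLines(c("format-version: 1.2", "", unlist(stanzas)), path)
  invisible(path)
}
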