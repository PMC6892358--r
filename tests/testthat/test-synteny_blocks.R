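make_feats <- function(ids, chrom, starts, taxon) {
  data.frame(feature_id = ids, symbol = ids, taxon_id = as.integer(taxon),
             chromosome = chrom, start = starts, end = starts + 99,
             strand = "+", feature_type = "gene", stringsAsFactors = FALSE)
}

test_that("one-to-one pairs on single chromosomes get consecutive ordinals", {
  ref <- make_feats(paste0("a", 1:5), "1", (1:5) * 1000, 1)
  comp <- make_feats(paste0("b", 1:5), "1", (1:5) * 1000, 2)
  idx <- index_anchors(ref, comp, data.frame(ref_id = paste0("a", 1:5),
                                             comp_id = paste0("b", 1:5)))
  expect_equal(idx$ref$ordinal, 1:5)
  expect_equal(idx$comp$ordinal, 1:5)
  expect_equal(idx$anchors$comp_ord, 1:5)
})

test_that("drop_ambiguous removes every pair touching a multi-mapped gene", {
  ref <- make_feats(paste0("a", 1:3), "1", (1:3) * 1000, 1)
  comp <- make_feats(paste0("b", 1:4), "1", (1:4) * 1000, 2)
  pairs <- data.frame(ref_id = c("a1", "a1", "a2", "a3"),
                      comp_id = c("b1", "b2", "b3", "b4"))
  idx <- index_anchors(ref, comp, pairs, "drop_ambiguous")
  expect_false("a1" %in% idx$anchors$ref_id)
  expect_equal(sort(idx$anchors$ref_id), c("a2", "a3"))
})

test_that("keep_first_by_position yields an injective relation", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    ref <- make_feats(sprintf("a%02d", 1:n), "1", sample.int(1e5, n), 1)
    comp <- make_feats(sprintf("b%02d", 1:n), "1", sample.int(1e5, n), 2)
    pairs <- data.frame(ref_id = sprintf("a%02d", 1:n),
                        comp_id = sprintf("b%02d", 1:n))
    # add ~10% multi-mappings
    extra <- data.frame(ref_id = sprintf("a%02d", sample.int(n, 3)),
                        comp_id = sprintf("b%02d", sample.int(n, 3)))
    idx <- index_anchors(ref, comp, rbind(pairs, extra),
                         "keep_first_by_position")
    a <- idx$anchors
    # pairwise scan: no gene on either side occurs twice
    for (i in seq_len(nrow(a) - 1))
      for (j in (i + 1):nrow(a)) {
        expect_false(a$ref_id[i] == a$ref_id[j])
        expect_false(a$comp_id[i] == a$comp_id[j])
      }
  }
})

test_that("pairs naming unknown features are rejected with offenders listed", {
  ref <- make_feats("a1", "1", 1000, 1)
  comp <- make_feats("b1", "1", 1000, 2)
  expect_error(index_anchors(ref, comp,
                             data.frame(ref_id = "a1", comp_id = "bX")),
               "bX")
})

test_that("the scanner handles the canonical ordinal sequences", {
  run <- function(perm, min_anchors = 2)
    compute_blocks(anchor_index_from_permutation(perm),
                   min_anchors = min_anchors)

  b <- run(1:5)
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "+")
  expect_equal(c(b$ref_start, b$ref_end), c(1000, 5499))
  expect_equal(c(b$comp_start, b$comp_end), c(1000, 5499))

  b <- run(c(1, 2, 3, 5, 4))
  expect_equal(nrow(b), 2)
  expect_equal(b$orientation, c("+", "-"))
  expect_equal(nrow(b$anchors[[1]]), 3)
  expect_equal(nrow(b$anchors[[2]]), 2)

  b <- run(5:1)
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "-")

  expect_equal(nrow(run(c(1, 3, 5, 2, 4))), 0)
})

test_that("blocks partition anchors at min_anchors = 1 and nest in min_anchors", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    idx <- anchor_index_from_permutation(random_permutation(n))
    b1 <- compute_blocks(idx, min_anchors = 1)
    members <- unname(unlist(lapply(b1$anchors, function(a) a$ref_id)))
    expect_equal(sort(members), sort(idx$anchors$ref_id))  # disjoint union
    expect_equal(length(members), n)

    b2 <- compute_blocks(idx, min_anchors = 2)
    b3 <- compute_blocks(idx, min_anchors = 3)
    key <- function(b) paste(b$ref_start, b$ref_end, b$comp_start, b$comp_end)
    expect_true(all(key(b3) %in% key(b2)))
    expect_true(all(key(b2) %in% key(b1)))
  }
})

test_that("reversing the comparison genome flips every orientation", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    perm <- random_permutation(n)
    fwd <- compute_blocks(anchor_index_from_permutation(perm))
    rev_ <- compute_blocks(anchor_index_from_permutation(n + 1 - perm))
    expect_equal(nrow(fwd), nrow(rev_))
    expect_equal(rev_$orientation, chartr("+-", "-+", fwd$orientation))
    expect_equal(rev_$ref_start, fwd$ref_start)
    expect_equal(rev_$ref_end, fwd$ref_end)
  }
})

test_that("the scanner agrees with the brute-force maximal-run oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    perm <- random_permutation(n)
    ref_chr <- sort(sample(c("1", "2"), n, TRUE))
    comp_chr <- sort(sample(c("1", "2"), n, TRUE))
    idx <- anchor_index_from_permutation(perm, ref_chr, comp_chr)
    got <- compute_blocks(idx, min_anchors = 2)
    exp <- oracle_blocks(idx, min_anchors = 2)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(exp))
      for (col in names(exp)) expect_equal(got[[col]], exp[[col]])
    }
    # boundaries are the outer limits of member genes
    for (i in seq_len(nrow(got))) {
      anc <- got$anchors[[i]]
      expect_equal(got$ref_start[i], min(anc$ref_start))
      expect_equal(got$ref_end[i], max(anc$ref_end))
      expect_equal(got$comp_start[i], min(anc$comp_start))
      expect_equal(got$comp_end[i], max(anc$comp_end))
    }
  }
})

test_that("monotonic mode accepts constant-sign jumps the default rejects", {
  idx <- anchor_index_from_permutation(c(1, 3, 5, 2, 4))
  expect_equal(nrow(compute_blocks(idx, mode = "consecutive")), 0)
  relaxed <- compute_blocks(idx, mode = "monotonic")
  expect_equal(nrow(relaxed), 2)
  expect_equal(relaxed$orientation, c("+", "+"))
  expect_equal(unname(vapply(relaxed$anchors, nrow, integer(1))), c(3L, 2L))
})

test_that("the worked block record parses to the documented fields", {
  tmp <- withr::local_tempfile()
  writeLines(paste("1", "10090", "3205901", "9299878",
                   "8", "9606", "49909789", "55526155",
                   "-", "ID=SynBlock:mmhs:1", sep = "\t"), tmp)
  b <- read_block_file(tmp)
  expect_equal(nrow(b), 1)
  expect_equal(b$comp_chr, "8")
  expect_equal(b$comp_taxon, 9606L)
  expect_equal(b$comp_start, 49909789)
  expect_equal(b$comp_end, 55526155)
  expect_equal(b$orientation, "-")
  expect_equal(b$block_id, "SynBlock:mmhs:1")
})

test_that("block file reading validates structure", {
  tmp <- withr::local_tempfile()
  writeLines(character(), tmp)
  expect_equal(nrow(read_block_file(tmp)), 0)

  writeLines("1\t10090\t1\t2\t8\t9606\t3", tmp)
  expect_error(read_block_file(tmp), "line 1.*10")

  writeLines("1\t10090\t1\t2\t8\t9606\t3\t4\t*\tID=x", tmp)
  expect_error(read_block_file(tmp), "orientation")

  writeLines(c("1\t10090\t1\t2\t8\t9606\t3\t4\t+\tID=x",
               "2\t10090\t1\t2\t8\t9606\t3\t4\t-\tID=x"), tmp)
  expect_error(read_block_file(tmp), "duplicate block ID")

  # bare identifiers are accepted too
  writeLines("1\t10090\t1\t2\t8\t9606\t3\t4\t+\tblk1", tmp)
  expect_equal(read_block_file(tmp)$block_id, "blk1")
})

test_that("random blocks survive a write/read round trip", {
  set.seed(3)
  n <- 50
  start_r <- sample.int(1e8, n); start_c <- sample.int(1e8, n)
  blocks <- data.frame(
    ref_chr = sample(c(as.character(1:19), "X"), n, TRUE),
    ref_taxon = 10090L, ref_start = start_r,
    ref_end = start_r + sample.int(1e6, n),
    comp_chr = sample(c(as.character(1:22), "X"), n, TRUE),
    comp_taxon = 9606L, comp_start = start_c,
    comp_end = start_c + sample.int(1e6, n),
    orientation = sample(c("+", "-"), n, TRUE),
    block_id = sprintf("SynBlock:mmhs:%d", 1:n), stringsAsFactors = FALSE)
  blocks$anchors <- I(rep(list(NULL), n))
  class(blocks) <- c("synteny_blocks", "data.frame")
  tmp <- withr::local_tempfile()
  write_block_file(blocks, tmp)
  back <- read_block_file(tmp)
  for (col in setdiff(names(blocks), "anchors"))
    expect_equal(back[[col]], blocks[[col]])
})
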