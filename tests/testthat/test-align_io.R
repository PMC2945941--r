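test_that("paired FASTA reading validates records and reports offsets", {
  f <- write_tmp_fasta(list(b1_anc = "ACGT", b1_desc = "ACAT"))
  blocks <- read_alignment_blocks(f, "paired_fasta")
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_columns, 4)
  expect_equal(blocks[[1]]$descendant, "ACAT")

  bad <- write_tmp_fasta(list(b1_anc = "ACG-T", b1_desc = "ACXGT"))
  expect_error(read_alignment_blocks(bad, "paired_fasta"),
               "illegal character 'X' at offset 3")

  uneq <- write_tmp_fasta(list(b1_anc = "ACGT", b1_desc = "ACG"))
  expect_error(read_alignment_blocks(uneq, "paired_fasta"), "lengths differ")
})

test_that("lowercase input is uppercased and both-gap columns are dropped", {
  f <- write_tmp_fasta(list(b1_anc = "ac-Gt", b1_desc = "AC-at"))
  expect_message(blocks <- read_alignment_blocks(f, "paired_fasta"),
                 "dropped 1 columns")
  expect_equal(blocks[[1]]$ancestor, "ACGT")
  expect_equal(blocks[[1]]$descendant, "ACAT")
})

test_that("MAF reading selects species by prefix and skips incomplete blocks", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c(
    "##maf version=1", "",
    "a score=1",
    "s anc.chr1 10 4 + 100 ACGT",
    "s dsc.chr1 20 4 + 200 ACAT", "",
    "a score=2",
    "s anc.chr2 5 3 + 100 GGG", "",       # descendant missing -> skipped
    "a score=3",
    "s anc.chr3 0 4 + 100 AC-T",
    "s dsc.chr3 0 5 + 200 ACTTT"), maf)   # unequal lengths -> error? no: 4 vs 5 chars
  expect_error(read_alignment_blocks(maf, "maf", "anc", "dsc"),
               "lengths differ")
  writeLines(c(
    "##maf version=1", "",
    "a score=1",
    "s anc.chr1 10 4 + 100 ACGT",
    "s dsc.chr1 20 4 + 200 ACAT", "",
    "a score=2",
    "s anc.chr2 5 3 + 100 GGG", "",
    "a score=3",
    "s anc.chr3 0 5 + 100 AC-TT",
    "s dsc.chr3 0 5 + 200 ACTTT"), maf)
  expect_message(blocks <- read_alignment_blocks(maf, "maf", "anc", "dsc"),
                 "skipped 1 MAF blocks")
  expect_length(blocks, 2)
  expect_equal(attr(blocks, "skipped"), 1L)
  expect_equal(blocks[[1]]$source_coords$name, "anc.chr1")
  expect_equal(blocks[[1]]$source_coords$start, 10)
})

test_that("block filters apply the contiguity and gap-excess rules exactly", {
  # 9 vs 10 contiguous both-non-gap columns (max run 9 -> removed)
  b9 <- alignment_block(paste0(strrep("A", 9), "-", strrep("A", 9)),
                        strrep("A", 19), "b9")
  b10 <- alignment_block(strrep("A", 10), strrep("C", 10), "b10")
  # 6 gap-containing vs 5 aligned columns, but run of 5 also fails contiguity;
  # give it a long tail so only the gap-excess rule can remove it
  b_gap <- alignment_block(paste0(strrep("-", 12), strrep("A", 11)),
                           strrep("A", 23), "bgap")
  expect_message(
    kept <- filter_alignment_blocks(list(b9, b10, b_gap),
                                    min_contiguous_nongap = 10),
    "removed")
  expect_equal(vapply(kept, `[[`, "", "block_id"), "b10")
  # idempotence
  expect_silent(kept2 <- filter_alignment_blocks(kept, 10))
  expect_equal(length(kept2), length(kept))
})

test_that("gap-excess rule counts columns, with N as a non-gap base", {
  # 6 gapped, 5 aligned -> removed; 5 gapped, 6 aligned -> retained
  mk <- function(n_gap, n_aln) {
    alignment_block(paste0(strrep("-", n_gap), strrep("A", n_aln)),
                    paste0(strrep("A", n_gap), strrep("N", n_aln)), "x")
  }
  expect_length(filter_alignment_blocks(list(mk(6, 5)), 1), 0)
  expect_length(filter_alignment_blocks(list(mk(5, 6)), 1), 1)
})

test_that("windows are maximal gap-free N-free runs", {
  b <- cacgca_block()
  w2 <- alignment_windows(b, 2)
  expect_equal(w2$ancestor, c("CA", "AC", "CG", "GC", "CA"))
  expect_equal(w2$descendant, c("CA", "AT", "TG", "GC", "CA"))

  b2 <- alignment_block("AC-GT", "ACAGT")
  expect_equal(nrow(alignment_windows(b2, 3)), 0)
  expect_equal(nrow(alignment_windows(b2, 2)), 2)

  b3 <- alignment_block("ACNGT", "ACAGT")   # N breaks runs like a gap
  expect_equal(nrow(alignment_windows(b3, 3)), 0)
})

test_that("CpG window exclusion removes run-adjacent windows too", {
  w <- alignment_windows(cacgca_block(), 2, exclude_ancestral_cpg = TRUE)
  expect_equal(w$ancestor, c("CA", "CA"))
  expect_equal(w$start, c(1, 5))
  # the GC window (G preceded by ancestral C) and AC window (C followed by
  # ancestral G) are gone along with CG itself
  expect_false(any(w$ancestor %in% c("AC", "CG", "GC")))
})

test_that("window count and prefix/suffix consistency properties hold", {
  for (seed in 1:5) {
    b <- random_block(300, seed, gap_rate = 0.03, n_rate = 0.01)
    gapfree <- random_block(200, seed + 100)
    for (L in 1:4)
      expect_equal(nrow(alignment_windows(gapfree, L)), 200 - L + 1)
    for (L in 1:3) {
      wL <- alignment_windows(b, L)
      wL1 <- alignment_windows(b, L + 1)
      if (nrow(wL1)) {
        expect_true(all(substr(wL1$ancestor, 1, L) %in% wL$ancestor))
        expect_true(all(substr(wL1$ancestor, 2, L + 1) %in% wL$ancestor))
      }
    }
  }
})

test_that("BED masks restrict blocks by ancestral coordinate", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t105\t110", bed)    # 0-based half-open
  b <- alignment_block("AAAAACCCCCGGGGG", "AAAAACCCCCGGGGG", "m",
                       source_coords = list(name = "chr1", start = 100,
                                            end = 115, strand = "+"))
  masked <- apply_bed_mask(list(b), bed)
  expect_length(masked, 1)
  expect_equal(masked[[1]]$ancestor, "CCCCC")
  expect_equal(masked[[1]]$source_coords$start, 105)
})

test_that("FASTA and MAF writers round-trip blocks", {
  blocks <- list(alignment_block("ACGT-A", "ACATAA", "blk1"),
                 alignment_block("GGGG", "GGCG", "blk2"))
  fa <- tempfile(fileext = ".fa")
  write_paired_fasta(blocks, fa)
  rt <- read_alignment_blocks(fa, "paired_fasta")
  expect_equal(rt[[1]]$ancestor, "ACGT-A")
  expect_equal(rt[[2]]$descendant, "GGCG")

  maf <- tempfile(fileext = ".maf")
  write_maf(blocks, maf, "anc", "dsc")
  rt2 <- read_alignment_blocks(maf, "maf", "anc", "dsc")
  expect_equal(rt2[[1]]$ancestor, "ACGT-A")
  expect_equal(rt2[[2]]$descendant, "GGCG")
})
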