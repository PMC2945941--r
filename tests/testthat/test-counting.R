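test_that("worked-example counts match hand enumeration", {
  tab <- cacgca_table(3)
  # L = 1
  expect_equal(unname(pattern_proportion(tab, "C->C")), 2 / 3)
  expect_equal(tab$windows[["1"]], 6)
  expect_equal(unname(pattern_proportion(tab, "C->T")), 1 / 3)
  a1 <- tab$anc_tabs[["1"]]
  expect_equal(a1$count[match(c(1, 0, 2), a1$anc)], c(3, 2, 1))  # C,A,G
  # L = 2: CA->CA x2, AC->AT, CG->TG, GC->GC
  expect_equal(tab$windows[["2"]], 5)
  t2 <- tab$tabs[["2"]]
  expect_equal(sum(t2$count), 5)
  expect_equal(unname(pattern_proportion(tab, "CG->TG")), 1)
  # L = 3: 4 windows x 2 masks = 8 total counts
  expect_equal(tab$windows[["3"]], 4)
  expect_equal(sum(tab$tabs[["3"]]$count), 8)
})

test_that("proportion is undefined (NA) for unobserved ancestral words", {
  tab <- cacgca_table(2)
  expect_true(is.na(pattern_proportion(tab, "TT->TT")))
  # unobserved pattern over an observed ancestor is 0, not NA
  expect_equal(unname(pattern_proportion(tab, "CA->CG")), 0)
})

test_that("frequencies normalise per length", {
  tab <- cacgca_table(3)
  expect_equal(unname(pattern_frequency(tab, "CG->TG")), 0.2)
  expect_equal(unname(pattern_frequency(tab, "CNC->TNC")), 1 / 8)
  for (seed in 1:3) {
    b <- random_block(400, seed, gap_rate = 0.02)
    tt <- count_patterns(list(b), 4)
    for (L in 1:4) {
      tabL <- tt$tabs[[as.character(L)]]
      if (!nrow(tabL)) next
      f <- sum(tabL$count) / (tt$windows[[as.character(L)]] * 2^max(L - 2, 0))
      expect_equal(f, 1, tolerance = 1e-12)
    }
  }
})

test_that("count tables satisfy their internal invariants on random input", {
  for (seed in 1:4) {
    blocks <- lapply(1:3, function(k)
      random_block(300, seed * 10 + k, gap_rate = 0.03, n_rate = 0.01))
    tab <- count_patterns(blocks, 4)
    for (L in 1:4) {
      tL <- tab$tabs[[as.character(L)]]
      aL <- tab$anc_tabs[[as.character(L)]]
      if (!nrow(tL)) next
      # pattern count never exceeds its ancestral count
      acnt <- aL$count[match(tL$anc, aL$anc)]
      expect_true(all(tL$count <= acnt))
      # per-mask sums equal the window count
      mb <- ctxbias:::mask_bits(tL$anc, L)
      sums <- tapply(tL$count, mb, sum)
      expect_true(all(sums == tab$windows[[as.character(L)]]))
      # ancestral counts per mask sum to the window count too
      amb <- ctxbias:::mask_bits(aL$anc, L)
      expect_true(all(tapply(aL$count, amb, sum) == tab$windows[[as.character(L)]]))
    }
  }
})

test_that("counting agrees with the brute-force window scan", {
  blocks <- list(random_block(120, 42, gap_rate = 0.05),
                 random_block(80, 43, n_rate = 0.03))
  tab <- count_patterns(blocks, 3)
  for (L in 1:3) {
    obs <- oracle_observed_patterns(blocks, L)
    tL <- tab$tabs[[as.character(L)]]
    expect_equal(nrow(tL), nrow(obs))
    key <- ctxbias:::format_patterns(L, tL$anc, tL$desc)
    expect_equal(tL$count[match(obs$pattern, key)], as.numeric(obs$count))
  }
})

test_that("counting is additive across block sets", {
  A <- list(random_block(200, 1, gap_rate = 0.02))
  B <- list(random_block(150, 2), random_block(90, 3, n_rate = 0.02))
  tAB <- count_patterns(c(A, B), 3)
  tA <- count_patterns(A, 3)
  tB <- count_patterns(B, 3)
  for (L in 1:3) {
    expect_equal(tAB$windows[[as.character(L)]],
                 tA$windows[[as.character(L)]] + tB$windows[[as.character(L)]])
    key <- function(t) {
      tt <- t$tabs[[as.character(L)]]
      setNames(tt$count, ctxbias:::format_patterns(L, tt$anc, tt$desc))
    }
    kA <- key(tA); kB <- key(tB); kAB <- key(tAB)
    all_pat <- union(names(kA), names(kB))
    merged <- ifelse(is.na(kA[all_pat]), 0, kA[all_pat]) +
      ifelse(is.na(kB[all_pat]), 0, kB[all_pat])
    expect_equal(unname(kAB[all_pat]), unname(merged))
  }
})

test_that("empty input yields an all-zero table, not an error", {
  tab <- count_patterns(list(), 3)
  expect_equal(unname(tab$windows), c(0, 0, 0))
})

test_that("TSV round trip preserves counts, windows and options", {
  tab <- count_patterns(list(random_block(250, 9, gap_rate = 0.02)), 3,
                        exclude_ancestral_cpg = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_count_table(tab, f)
  rt <- read_count_table(f)
  expect_equal(rt$windows, tab$windows)
  expect_true(rt$exclude_ancestral_cpg)
  expect_equal(rt$n_columns, tab$n_columns)
  for (L in 1:3)
    expect_equal(rt$tabs[[as.character(L)]], tab$tabs[[as.character(L)]])
})

test_that("window-level CpG exclusion reduces window counts coherently", {
  tab <- count_patterns(list(cacgca_block()), 2, exclude_ancestral_cpg = TRUE)
  expect_equal(tab$windows[["2"]], 2)
  t2 <- tab$tabs[["2"]]
  expect_equal(ctxbias:::format_patterns(2, t2$anc, t2$desc), "CA->CA")
  expect_equal(t2$count, 2)
})
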