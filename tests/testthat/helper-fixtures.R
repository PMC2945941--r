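# Shared fixtures built in code.

# the worked 6-bp example: one CpG deamination (C->T at column 3)
cacgca_block <- function() alignment_block("CACGCA", "CATGCA", "worked")

cacgca_table <- function(Lmax = 3) count_patterns(list(cacgca_block()), Lmax)

# random gap-containing block pair for property tests
random_block <- function(n, seed, gap_rate = 0, n_rate = 0, div = 0.05) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  d <- ifelse(stats::runif(n) < div,
              sample(c("A", "C", "G", "T"), n, replace = TRUE), a)
  if (gap_rate > 0) {
    ga <- stats::runif(n) < gap_rate
    gd <- stats::runif(n) < gap_rate
    both <- ga & gd
    ga[both] <- FALSE          # keep the pair valid: never gap both
    a[ga] <- "-"
    d[gd] <- "-"
  }
  if (n_rate > 0) {
    a[stats::runif(n) < n_rate] <- "N"
    d[stats::runif(n) < n_rate] <- "N"
  }
  alignment_block(paste(a, collapse = ""), paste(d, collapse = ""),
                  sprintf("rb%d", seed))
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
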