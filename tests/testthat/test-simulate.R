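test_that("ancestor generation is deterministic and respects composition", {
  expect_equal(generate_ancestor(100, c(1, 0, 0, 0), seed = 1),
               strrep("A", 100))
  expect_identical(generate_ancestor(5000, seed = 7),
                   generate_ancestor(5000, seed = 7))
  a <- generate_ancestor(1e6, seed = 2)
  frac <- table(strsplit(a, "")[[1]]) / 1e6
  # binomial 5 SD band around 0.25
  expect_true(all(abs(frac - 0.25) < 5 * sqrt(0.25 * 0.75 / 1e6)))
  expect_error(generate_ancestor(10, c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})

test_that("single-base model validation and defaults are row-stochastic", {
  m <- default_single_base_model()
  expect_equal(rowSums(m), setNames(rep(1, 4), c("A", "C", "G", "T")))
  # C row mirrors the observed divergence shape: transition 0.6%,
  # transversions 0.13%, stays ~99.1%
  expect_equal(unname(m["C", "T"]), 0.006)
  expect_equal(unname(m["C", "A"]), 0.0013)
  expect_equal(unname(m["C", "C"]), 1 - 0.006 - 2 * 0.0013)
  expect_error(single_base_model(matrix(0.3, 4, 4)), "sum to 1")
})

test_that("no-bias mutation recovers the model rates", {
  anc <- generate_ancestor(1e6, seed = 3)
  expect_equal(mutate_no_bias(anc, diag(4), seed = 1), anc)
  model <- default_single_base_model()
  desc <- mutate_no_bias(anc, model, seed = 4)
  tab <- count_patterns(as_alignment_blocks(anc, desc), 1)
  # C -> T fraction within 5 binomial SDs of 0.006
  pCT <- unname(pattern_proportion(tab, "C->T"))
  nC <- sum(strsplit(anc, "")[[1]] == "C")
  expect_lt(abs(pCT - 0.006), 5 * sqrt(0.006 * 0.994 / nC))
})

test_that("estimate_model round-trips: hand example and recovery", {
  # worked example extended with a TT column so all four ancestral bases
  # are observed (the C row is unchanged)
  tab <- count_patterns(list(alignment_block("CACGCAT", "CATGCAT")), 1)
  m <- estimate_model(tab)
  expect_equal(unname(m["C", ]), c(0, 2 / 3, 0, 1 / 3))
  expect_equal(unname(m["A", ]), c(1, 0, 0, 0))
  # identity data -> identity matrix
  b <- alignment_block("ACGTACGT", "ACGTACGT")
  expect_equal(unname(unclass(estimate_model(count_patterns(list(b), 1)))),
               diag(4), ignore_attr = TRUE)
  # model recovery within 5 SD per entry at 1e6 sites
  model <- default_single_base_model()
  anc <- generate_ancestor(1e6, seed = 5)
  desc <- mutate_no_bias(anc, model, seed = 6)
  est <- estimate_model(count_patterns(as_alignment_blocks(anc, desc), 1))
  n_per_base <- 2.5e5
  tol <- 5 * sqrt(as.vector(model) * (1 - as.vector(model)) / n_per_base)
  expect_true(all(abs(as.vector(est) - as.vector(model)) < tol))
  expect_error(estimate_model(count_patterns(list(
    alignment_block("AAAA", "AAAA")), 1)), "all four")
})

test_that("context rules validate their template and focal base", {
  expect_error(context_rule("C", "T", "AG", 1, 2), "focal position")
  expect_error(context_rule("C", "C", "CG", 1, 2), "from != to")
  expect_s3_class(context_rule("T", "C", "TNG", 1, 5), "context_rule")
})

test_that("empty rule set reproduces mutate_no_bias exactly", {
  anc <- generate_ancestor(2e4, seed = 8)
  model <- default_single_base_model()
  expect_identical(mutate_with_context(anc, model, list(), seed = 9),
                   mutate_no_bias(anc, model, seed = 9))
})

test_that("expected-proportion oracle matches hand enumeration and closed form", {
  model <- default_single_base_model()
  rule <- context_rule("C", "T", "CG", 1, 10)
  # hand enumeration for pr(C->T) on a uniform ancestor: next base G with
  # probability 1/4 multiplies the rate by 10
  pCT <- expected_pattern_proportion("C->T", model, list(rule))
  expect_equal(pCT, 0.006 * (1 + 9 / 4), tolerance = 1e-12)
  # pr(CG->TG) = 10 * p_CT * p_GG
  pCGTG <- expected_pattern_proportion("CG->TG", model, list(rule))
  expect_equal(pCGTG, 10 * 0.006 * (1 - 0.006 - 2 * 0.0013), tolerance = 1e-12)
  # closed form for the target rho: m / (1 + (m - 1) * qG)
  for (m in c(2, 5, 10)) {
    r <- context_rule("C", "T", "CG", 1, m)
    expect_equal(expected_rho("CG->TG", model, list(r)),
                 m / (1 + (m - 1) / 4), tolerance = 1e-9)
  }
  # no rules: every rho is 1
  expect_equal(expected_rho("CG->TG", model, list()), 1, tolerance = 1e-12)
  expect_equal(expected_rho("TNG->CNG", model, list()), 1, tolerance = 1e-12)
})

test_that("context mutation hits the target rate in simulation", {
  rule <- context_rule("C", "T", "CG", 1, 10)
  model <- default_single_base_model()
  anc <- generate_ancestor(1e6, seed = 10)
  desc <- mutate_with_context(anc, model, list(rule), seed = 11)
  tab <- count_patterns(as_alignment_blocks(anc, desc), 2)
  pr_obs <- unname(pattern_proportion(tab, "CG->TG"))
  pr_exp <- expected_pattern_proportion("CG->TG", model, list(rule))
  n_cg <- 1e6 / 16
  expect_lt(abs(pr_obs - pr_exp), 5 * sqrt(pr_exp * (1 - pr_exp) / n_cg))
})

test_that("oversized multipliers are rejected at renormalisation", {
  rule <- context_rule("C", "T", "CG", 1, 500)
  expect_error(
    mutate_with_context(generate_ancestor(1000, seed = 1),
                        default_single_base_model(), list(rule), seed = 2),
    "below 0")
})

test_that("sequencing-error injection matches its nominal rate", {
  blocks <- simulate_alignment(1e6, model = diag(4), seed = 12)
  same <- inject_errors(blocks, 0, 0, seed = 13)
  expect_identical(same[[1]]$ancestor, blocks[[1]]$ancestor)
  pert <- inject_errors(blocks, 0, 0.001, seed = 14)
  tab <- count_patterns(pert, 1)
  t1 <- tab$tabs[["1"]]
  changed <- sum(t1$count[t1$anc != t1$desc]) / sum(t1$count)
  expect_lt(abs(changed - 0.001), 5 * sqrt(0.001 * 0.999 / 1e6))
})

test_that("block wrapping splits positionally with a remainder block", {
  anc <- generate_ancestor(25000, seed = 15)
  desc <- mutate_no_bias(anc, default_single_base_model(), seed = 16)
  blocks <- as_alignment_blocks(anc, desc, block_length = 10000)
  expect_length(blocks, 3)
  expect_equal(vapply(blocks, `[[`, 0, "n_columns"), c(10000, 10000, 5000))
  expect_equal(paste(vapply(blocks, `[[`, "", "ancestor"), collapse = ""), anc)
})

test_that("draft-level sequencing errors do not shift bias summaries", {
  # finished/draft error regime: 1e-4 (ancestor) and 7e-4 (descendant)
  rules <- list(context_rule("C", "T", "CG", 1, 10))
  blocks <- simulate_alignment(1e6, rules = rules, seed = 19)
  noisy <- inject_errors(blocks, 0.0001, 0.0007, seed = 20)
  st <- stat_total_context_bias(2)
  ci <- bootstrap_ci(blocks, st, n_boot = 100, seed = 21)
  clean_val <- ci$estimate
  noisy_val <- st$fn(count_patterns(noisy, 2))
  expect_lt(abs(noisy_val - clean_val), ci$ci_high - ci$ci_low)
})

test_that("simulators are deterministic end to end", {
  a <- simulate_alignment(2e4, rules = list(context_rule("C", "T", "CG", 1, 5)),
                          seed = 17)
  b <- simulate_alignment(2e4, rules = list(context_rule("C", "T", "CG", 1, 5)),
                          seed = 17)
  expect_identical(vapply(a, `[[`, "", "descendant"),
                   vapply(b, `[[`, "", "descendant"))
})
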