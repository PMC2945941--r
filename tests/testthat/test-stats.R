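test_that("bh_fdr reproduces the hand-computed step-up example", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, -0.1)), "0, 1")
  expect_equal(bh_fdr(numeric(0)), numeric(0))
})

test_that("bh_fdr agrees exactly with the brute-force step-up oracle", {
  set.seed(17)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("bootstrap CI bounds are the stated order statistics", {
  blocks <- replicate(5, cacgca_block(), simplify = FALSE)
  ci <- bootstrap_ci(blocks, stat_pattern("CG->TG", what = "rho"),
                     n_boot = 100, seed = 3)
  reps <- attr(ci, "replicates")[, 1]
  s <- sort(reps)
  expect_equal(ci$ci_low, s[floor(0.025 * 100) + 1])
  expect_equal(ci$ci_high, s[100 - floor(0.025 * 100)])
  # identical blocks: every replicate equals the point estimate
  expect_equal(ci$ci_low, ci$estimate)
  expect_equal(ci$ci_high, ci$estimate)
  expect_equal(ci$estimate, 3)
})

test_that("bootstrap is bit-reproducible given the seed", {
  blocks <- simulate_alignment(3e4, block_length = 3000, seed = 5)
  st <- stat_pattern(c("CG->TG", "AT->GT"), what = "both")
  a <- bootstrap_ci(blocks, st, n_boot = 60, seed = 11)
  b <- bootstrap_ci(blocks, st, n_boot = 60, seed = 11)
  c <- bootstrap_ci(blocks, st, n_boot = 60, seed = 12)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))
  expect_false(identical(attr(a, "replicates"), attr(c, "replicates")))
})

test_that("bootstrap replicates reach the original column count", {
  blocks <- simulate_alignment(2e4, block_length = 1500, seed = 6)
  cols <- vapply(blocks, `[[`, 0, "n_columns")
  set.seed(1)
  for (r in 1:20) {
    idx <- ctxbias:::.sample_until(cols, sum(cols))
    got <- sum(cols[idx])
    expect_gte(got, sum(cols))
    # removing the final (overshooting) block drops below the target
    expect_lt(got - cols[idx[length(idx)]], sum(cols))
  }
})

test_that("statistics flagged undefined in most replicates yield NA CIs", {
  # TT->TT never observed: rho undefined in every replicate
  blocks <- replicate(3, cacgca_block(), simplify = FALSE)
  ci <- bootstrap_ci(blocks, stat_pattern("TT->TT", what = "rho"),
                     n_boot = 20, seed = 2)
  expect_true(is.na(ci$ci_low))
  expect_equal(ci$n_undefined, 20)
})

test_that("empirical p-values follow the add-one formula", {
  real <- data.frame(pattern = c("CG->TG", "AT->GT"),
                     context_bias = c(0.5, 0))
  controls <- lapply(1:10, function(k)
    data.frame(pattern = rep(c("CG->TG", "AT->GT"), each = 50),
               context_bias = rep(seq(0.001, 0.05, length.out = 50), 2)))
  res <- empirical_pvalues(real, controls, pooling = "per_length")
  # 1000 pooled nulls, all below 0.5 -> p = 1/1001
  expect_equal(res$p_value[1], 1 / 1001)
  # cb = 0: every null is >= 0 -> p = 1
  expect_equal(res$p_value[2], 1)
  # per-pattern pooling restricts the null to 500 values
  res2 <- empirical_pvalues(real, controls, pooling = "per_pattern")
  expect_equal(res2$p_value[1], 1 / 501)
  expect_equal(res2$n_null[1], 500)
  expect_error(empirical_pvalues(real, list()), "at least one")
})

test_that("empirical p-value counting matches a naive >= scan", {
  set.seed(23)
  real <- data.frame(pattern = rep("AC->AT", 20),
                     context_bias = rnorm(20, sd = 0.1))
  nulls <- data.frame(pattern = rep("AC->AT", 200),
                      context_bias = rnorm(200, sd = 0.1))
  res <- empirical_pvalues(real, list(nulls))
  naive <- vapply(abs(real$context_bias), function(x)
    (1 + sum(abs(nulls$context_bias) >= x)) / 201, 0)
  expect_equal(res$p_value, naive)
})

test_that("compare_total_bias is exact on byte-identical inputs", {
  A <- simulate_alignment(3e4, block_length = 3000, seed = 8)
  res <- compare_total_bias(A, A, L_set = 2, columns_per_sample = 3e4,
                            n_resamples = 40, seed = 4)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_A, res$mean_B)
})

test_that("compare_total_bias detects a strong injected difference", {
  A <- simulate_alignment(2e5,
    rules = list(context_rule("C", "T", "CG", 1, 10)), seed = 13,
    block_length = 5000)
  B <- simulate_alignment(2e5, seed = 14, block_length = 5000)
  res <- compare_total_bias(A, B, L_set = 2, columns_per_sample = 2e5,
                            n_resamples = 100, seed = 6)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_A, res$mean_B)
})

test_that("extreme column reuse triggers the overshoot warning", {
  A <- simulate_alignment(2e3, block_length = 1000, seed = 9)
  B <- simulate_alignment(2e3, block_length = 1000, seed = 10)
  expect_warning(
    compare_total_bias(A, B, L_set = 2, columns_per_sample = 5e5,
                       n_resamples = 10, seed = 2),
    "extreme reuse")
})
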