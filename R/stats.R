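## ---------------------------------------------------------------------------
## Block bootstrap, empirical-null p-values, BH FDR, dataset comparison
## ---------------------------------------------------------------------------

## Sample block indices with replacement until the cumulative column count
## first reaches or exceeds `target`; the overshooting block is kept whole
## (truncating it would bias window counts).  Uses the current RNG state.
.sample_until <- function(columns, target) {
  n_b <- length(columns)
  idx <- integer(0)
  tot <- 0
  mean_cols <- mean(columns)
  while (tot < target) {
    need <- max(16L, ceiling((target - tot) / mean_cols) + 8L)
    draw <- sample.int(n_b, need, replace = TRUE)
    cs <- tot + cumsum(columns[draw])
    k <- which(cs >= target)
    if (length(k)) {
      idx <- c(idx, draw[seq_len(k[1L])])
      tot <- cs[k[1L]]
    } else {
      idx <- c(idx, draw)
      tot <- cs[length(cs)]
    }
  }
  idx
}

## (L, kept-mask) combinations needed to evaluate rho for `patterns`,
## i.e. the patterns themselves plus their full subpattern closure.
.pattern_lmasks <- function(patterns) {
  closure <- unique(c(patterns,
                      unlist(lapply(patterns, subpatterns), use.names = FALSE)))
  pp <- parse_patterns(closure)
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(pp))) {
    kept <- which(digit_at(pp$anc[i], pp$L[i], seq_len(pp$L[i])) != 4)
    key <- paste0(pp$L[i], ":", paste(kept, collapse = ","))
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(L = pp$L[i], kept = kept)
  }
  out
}

.all_lmasks <- function(Lmax) {
  out <- list()
  for (L in seq_len(Lmax))
    for (kept in .all_masks(L))
      out[[length(out) + 1L]] <- list(L = L, kept = kept)
  out
}

## Compile the subpattern closure of `patterns` into a flat plan evaluated
## with plain match() arithmetic: per-replicate evaluation must not pay the
## general engine's per-call overhead inside bootstrap loops.  Uses the
## recursive definition (equivalent to the fast algorithm).
.compile_rho_plan <- function(patterns = NULL, rows = NULL) {
  P7 <- 5^7
  keyof <- function(L, anc, desc) (L * P7 + anc) * P7 + desc
  req <- if (is.null(rows)) parse_patterns(patterns)[, list(L, anc, desc)]
         else as.data.table(rows)[, list(L, anc, desc)]
  subs <- .sub_rows(req)
  all_rows <- unique(rbindlist(list(unique(req), subs)))
  n <- nrow(all_rows)
  all_rows[, mb := mask_bits(anc, L[1L]), by = L]
  keys <- keyof(all_rows$L, all_rows$anc, all_rows$desc)
  m <- integer(n)
  sub_idx <- vector("list", n)
  pos <- seq_len(n)
  for (grp_i in split(pos, list(all_rows$L, all_rows$mb), drop = TRUE)) {
    L <- all_rows$L[grp_i[1L]]
    kept <- which(digit_at(all_rows$anc[grp_i[1L]], L, seq_len(L)) != 4)
    m[grp_i] <- length(kept)
    if (length(kept) == 1L) next
    info <- mask_info(L, kept)
    adig <- ddig <- vector("list", L)
    for (j in kept) {
      adig[[j]] <- digit_at(all_rows$anc[grp_i], L, j)
      ddig[[j]] <- digit_at(all_rows$desc[grp_i], L, j)
    }
    S <- length(info$subsets)
    km <- matrix(0, nrow = length(grp_i), ncol = S)
    for (s in seq_len(S)) {
      d <- info$subsets[[s]]
      km[, s] <- keyof(d$subL, .apply_descriptor(d, adig),
                       .apply_descriptor(d, ddig))
    }
    ## position-subset multiplicity is retained: repeated subpatterns
    ## contribute repeated rho factors to psi (psi(AA->AA) = rho(A->A)^2)
    im <- matrix(match(km, keys), nrow = length(grp_i), ncol = S)
    for (r in seq_along(grp_i)) sub_idx[[grp_i[r]]] <- im[r, ]
  }
  list(L = all_rows$L, anc = all_rows$anc, desc = all_rows$desc, m = m,
       order = order(m), sub_idx = sub_idx,
       req_idx = match(keyof(req$L, req$anc, req$desc), keys))
}

.eval_rho_plan <- function(plan, table) {
  n <- length(plan$L)
  pr <- rep(NA_real_, n)
  cnt_all <- numeric(n)
  P7 <- 5^7
  for (LL in unique(plan$L)) {
    i <- which(plan$L == LL)
    tab <- table$tabs[[as.character(LL)]]
    atab <- table$anc_tabs[[as.character(LL)]]
    if (is.null(tab)) stop(sprintf("count table has no counts at L=%d", LL))
    cnt <- tab$count[match(plan$anc[i] * P7 + plan$desc[i],
                           tab$anc * P7 + tab$desc)]
    cnt[is.na(cnt)] <- 0
    acnt <- atab$count[match(plan$anc[i], atab$anc)]
    pr[i] <- ifelse(is.na(acnt) | acnt == 0, NA_real_, cnt / acnt)
    cnt_all[i] <- cnt
  }
  rho <- rep(NA_real_, n)
  for (k in plan$order) {
    if (plan$m[k] == 1L) {
      rho[k] <- pr[k]
    } else {
      sv <- rho[plan$sub_idx[[k]]]
      if (is.na(pr[k]) || anyNA(sv)) next
      psi <- prod(sv)
      if (psi == 0) next
      rho[k] <- pr[k] / psi
    }
  }
  list(rho = rho[plan$req_idx], count = cnt_all[plan$req_idx],
       L = plan$L[plan$req_idx], rho_all = rho)
}

## Every pattern of length L: all gap masks, all base assignments at kept
## positions.  Tractable for L <= 3 (4368 patterns); used to precompile
## total-context-bias bootstrap statistics.
.enumerate_patterns <- function(L) {
  parts <- list()
  for (kept in .all_masks(L)) {
    nconst <- if (length(kept) < L)
      sum(4 * 5^(L - setdiff(seq_len(L), kept))) else 0
    m <- length(kept)
    g <- as.matrix(expand.grid(rep(list(0:3), m)))
    codes <- as.numeric(g %*% 5^(L - kept)) + nconst
    cmb <- expand.grid(anc = codes, desc = codes)
    parts[[length(parts) + 1L]] <- data.table(L = L, anc = cmb$anc,
                                              desc = cmb$desc)
  }
  rbindlist(parts)
}

#' Bootstrap statistics over a count table
#'
#' Statistic constructors for [bootstrap_ci()] and [compare_total_bias()].
#' Each returns a function of a `pattern_count_table` together with the
#' minimal set of (length, gap-mask) combinations that must be counted per
#' block, which keeps bootstrap replicates cheap.
#'
#' @param patterns character vector of pattern strings.
#' @param method rho algorithm.
#' @param what `"rho"`, `"context_bias"` or `"both"`.
#' @return An object of class `ctx_statistic`.
#' @export
stat_pattern <- function(patterns, what = c("both", "rho", "context_bias"),
                         method = c("fast", "recursive")) {
  what <- match.arg(what)
  method <- match.arg(method)
  force(patterns)
  plan <- .compile_rho_plan(patterns)
  fn <- function(table) {
    res <- .eval_rho_plan(plan, table)
    f <- res$count / (table$windows[as.character(res$L)] * n_gap_masks(res$L))
    cb <- ifelse(res$count == 0, 0, (res$rho - 1) * f)
    switch(what,
           rho = setNames(res$rho, paste0("rho:", patterns)),
           context_bias = setNames(cb, paste0("cb:", patterns)),
           both = c(setNames(res$rho, paste0("rho:", patterns)),
                    setNames(cb, paste0("cb:", patterns))))
  }
  structure(list(fn = fn, lmasks = .pattern_lmasks(patterns),
                 name = paste0("pattern:", paste(patterns, collapse = ","))),
            class = "ctx_statistic")
}

#' @rdname stat_pattern
#' @param L pattern length(s) for the total-context-bias statistic.
#' @param pattern_filter,weighting,exclude_ancestral_cpg passed to
#'   [total_context_bias()].
#' @export
stat_total_context_bias <- function(L, pattern_filter = "all",
                                    weighting = "frequency",
                                    exclude_ancestral_cpg = FALSE,
                                    method = "fast") {
  force(L)
  if (max(L) <= 3L) {
    ## precompiled plan over the full pattern universe of these lengths:
    ## bootstrap replicates then cost one plan evaluation each
    uni <- rbindlist(lapply(L, .enumerate_patterns))
    plan <- .compile_rho_plan(rows = uni)
    nsub <- unlist(lapply(L, function(LL) {
      u <- .enumerate_patterns(LL)
      .n_substitutions(LL, u$anc, u$desc)
    }), use.names = FALSE)
    has_cpg <- unlist(lapply(L, function(LL) {
      u <- .enumerate_patterns(LL)
      .anc_has_cpg(LL, u$anc)
    }), use.names = FALSE)
    sel0 <- switch(pattern_filter,
                   all = rep(TRUE, nrow(uni)),
                   substitutions_only = nsub > 0L,
                   single_substitution = nsub == 1L)
    if (exclude_ancestral_cpg) sel0 <- sel0 & !has_cpg
    uniL <- uni$L
    fn <- function(table) {
      ev <- .eval_rho_plan(plan, table)
      out <- vapply(L, function(LL) {
        i <- which(uniL == LL & sel0 & ev$count > 0)
        rr <- ev$rho[i]
        ok <- !is.na(rr)
        if (!any(ok)) return(NA_real_)
        if (weighting == "frequency") {
          f <- ev$count[i][ok] /
            (table$windows[[as.character(LL)]] * n_gap_masks(LL))
          sum(abs(rr[ok] - 1) * f)
        } else mean(abs(rr[ok] - 1))
      }, 0)
      setNames(out, paste0("total_context_bias:L", L))
    }
  } else {
    fn <- function(table) {
      v <- total_context_bias(table, L, pattern_filter = pattern_filter,
                              weighting = weighting,
                              exclude_ancestral_cpg = exclude_ancestral_cpg,
                              method = method)
      setNames(as.numeric(v), paste0("total_context_bias:L", L))
    }
  }
  structure(list(fn = fn, lmasks = .all_lmasks(max(L)),
                 name = paste0("total_context_bias:L",
                               paste(L, collapse = ","))),
            class = "ctx_statistic")
}

#' Block-bootstrap confidence intervals
#'
#' Each replicate resamples whole alignment blocks with replacement until
#' the replicate's column count first reaches or exceeds the original total
#' (the overshooting block is kept), recounts patterns, and evaluates the
#' statistic.  The confidence interval is the range of the middle 95% of
#' replicate values by order statistics: for `n_boot = 1000`, the 26th and
#' 975th smallest (the middle 950).  Deterministic given `seed`;
#' per-replicate substreams are drawn up front from the master seed.
#'
#' @param blocks an `alignment_blocks` list (>= 2 blocks).
#' @param statistic a `ctx_statistic` from [stat_pattern()] or
#'   [stat_total_context_bias()].
#' @param n_boot number of bootstrap replicates.
#' @param seed master RNG seed.
#' @param exclude_ancestral_cpg window-level CpG exclusion during counting.
#' @return `data.frame(target, estimate, se, ci_low, ci_high, n_boot,
#'   n_undefined, seed)`; a target whose statistic is undefined in more than
#'   half the replicates gets `NA` bounds.  The replicate value matrix is
#'   attached as attribute `"replicates"`.
#' @export
bootstrap_ci <- function(blocks, statistic, n_boot = 1000L, seed = 1L,
                         exclude_ancestral_cpg = FALSE) {
  stopifnot(length(blocks) >= 2L, n_boot >= 2L,
            inherits(statistic, "ctx_statistic"))
  bw <- .blockwise_counts(blocks, statistic$lmasks, exclude_ancestral_cpg)
  target_cols <- sum(bw$columns)
  point <- statistic$fn(.aggregate_block_counts(bw, seq_along(blocks)))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  vals <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  for (r in seq_len(n_boot)) {
    set.seed(rep_seeds[r])
    idx <- .sample_until(bw$columns, target_cols)
    vals[r, ] <- statistic$fn(.aggregate_block_counts(bw, idx))
  }
  out <- lapply(seq_along(point), function(j) {
    v <- vals[, j]
    ok <- !is.na(v)
    if (sum(!ok) > n_boot / 2) {
      return(data.frame(target = names(point)[j], estimate = point[j],
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        n_boot = n_boot, n_undefined = sum(!ok), seed = seed))
    }
    s <- sort(v[ok])
    n_ok <- length(s)
    drop <- floor(0.025 * n_ok)
    data.frame(target = names(point)[j], estimate = point[j],
               se = stats::sd(s), ci_low = s[drop + 1L], ci_high = s[n_ok - drop],
               n_boot = n_boot, n_undefined = sum(!ok), seed = seed)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "replicates") <- vals
  out
}

#' Empirical p-values against no-bias controls
#'
#' For each pattern, the p-value is the add-one-smoothed fraction of null
#' context-bias values at least as extreme (in absolute value) as the
#' observed one: `p = (1 + #{|null| >= |cb|}) / (1 + #null)`.  With
#' `pooling = "per_length"` the null pool is all same-length patterns across
#' all control replicates, giving p-value resolution much finer than one
#' over the number of controls; `"per_pattern"` restricts the null to the
#' same pattern.
#'
#' @param real `data.frame` with columns `pattern` and `context_bias`
#'   (e.g. from [bias_table()]).
#' @param controls list of such data.frames computed on no-bias control
#'   datasets built on the same ancestor (see [mutate_no_bias()]).
#' @param pooling `"per_length"` or `"per_pattern"`.
#' @return `real` with columns `p_value` and `n_null` appended.
#' @export
empirical_pvalues <- function(real, controls,
                              pooling = c("per_length", "per_pattern")) {
  pooling <- match.arg(pooling)
  if (!length(controls)) stop("at least one no-bias control table is required")
  if (!is.list(controls) || is.data.frame(controls)) controls <- list(controls)
  null_dt <- rbindlist(lapply(controls, function(x)
    data.table(pattern = x$pattern, cb = abs(x$context_bias))))
  null_dt <- null_dt[!is.na(cb)]
  if (!nrow(null_dt)) stop("empty null distribution")
  obs <- abs(real$context_bias)
  if (pooling == "per_length") {
    null_dt[, L := nchar(sub("->.*$", "", pattern))]
    realL <- nchar(sub("->.*$", "", real$pattern))
    p <- rep(NA_real_, length(obs))
    nn <- rep(0L, length(obs))
    for (L in unique(realL)) {
      s <- sort(null_dt$cb[null_dt$L == L])
      i <- which(realL == L)
      n <- length(s)
      ge <- n - findInterval(obs[i], s, left.open = TRUE)
      p[i] <- (1 + ge) / (1 + n)
      nn[i] <- n
    }
  } else {
    p <- rep(NA_real_, length(obs))
    nn <- rep(0L, length(obs))
    null_split <- split(null_dt$cb, null_dt$pattern)
    for (i in seq_along(obs)) {
      s <- null_split[[real$pattern[i]]]
      if (is.null(s)) next
      p[i] <- (1 + sum(s >= obs[i])) / (1 + length(s))
      nn[i] <- length(s)
    }
  }
  real$p_value <- p
  real$n_null <- nn
  real
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts p-values ascending and returns `q_(i) = min_{j >= i} p_(j) * m / j`
#' clipped to 1, in the original order.  Patterns with `q` below a chosen
#' false discovery rate (0.001 for genome-scale top-pattern lists) are
#' reported as significant.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.8))
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(scaled))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Compare total context bias between two datasets
#'
#' Controls for the sample-size dependence of total context bias by drawing,
#' from each dataset independently, `n_resamples` block-bootstrap samples of
#' a fixed column count and computing total context bias for each.  The two
#' resulting means are compared per length with a two-sample t statistic
#' allowing unequal variances; the two-sided p-value is obtained by
#' bootstrapping the t statistic after mean-centering both samples (so the
#' null of equal means holds).  Deterministic given `seed`; the same
#' resampling substream is used for both datasets, so byte-identical inputs
#' give `t = 0, p = 1` exactly.
#'
#' @param blocksA,blocksB `alignment_blocks` lists.
#' @param L_set integer vector of pattern lengths to compare.
#' @param columns_per_sample fixed column count per resample (the
#'   genome-scale default is 50 million; scale down for small data).
#' @param n_resamples bootstrap samples per dataset.
#' @param seed master RNG seed.
#' @param n_t_boot resamples for the t-statistic null distribution.
#' @param pattern_filter,weighting,exclude_ancestral_cpg,method passed to
#'   [total_context_bias()].
#' @return `data.frame(L, mean_A, mean_B, t_statistic, p_value, n_resamples,
#'   columns_per_sample)`.
#' @export
compare_total_bias <- function(blocksA, blocksB, L_set,
                               columns_per_sample = 50000000,
                               n_resamples = 1000L, seed = 1L,
                               n_t_boot = 999L,
                               pattern_filter = "all",
                               weighting = "frequency",
                               exclude_ancestral_cpg = FALSE,
                               method = "fast") {
  stopifnot(length(blocksA) >= 1L, length(blocksB) >= 1L, n_resamples >= 2L)
  statistic <- stat_total_context_bias(
    L_set, pattern_filter = pattern_filter, weighting = weighting,
    exclude_ancestral_cpg = exclude_ancestral_cpg, method = method)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_resamples)
  t_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  totA <- sum(vapply(blocksA, `[[`, 0, "n_columns"))
  totB <- sum(vapply(blocksB, `[[`, 0, "n_columns"))
  if (columns_per_sample > 100 * min(totA, totB))
    warning("columns_per_sample exceeds 100x the dataset size (extreme reuse)")
  resample <- function(blocks) {
    bw <- .blockwise_counts(blocks, statistic$lmasks, exclude_ancestral_cpg)
    vals <- matrix(NA_real_, n_resamples, length(L_set),
                   dimnames = list(NULL, as.character(L_set)))
    for (r in seq_len(n_resamples)) {
      set.seed(rep_seeds[r])
      idx <- .sample_until(bw$columns, columns_per_sample)
      vals[r, ] <- statistic$fn(.aggregate_block_counts(bw, idx))
    }
    vals
  }
  xA <- resample(blocksA)
  xB <- resample(blocksB)
  set.seed(t_seed)
  out <- lapply(seq_along(L_set), function(j) {
    a <- xA[, j]; b <- xB[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    na <- length(a); nb <- length(b)
    ## The two bootstrap distributions stand in for the sampling
    ## distributions of the two total-bias estimates, so the mean
    ## difference is scaled by sqrt(vA + vB) (unequal variances, one
    ## estimator draw each) -- not by the standard error of the bootstrap
    ## means, which would shrink with n_resamples and reject everything.
    den <- sqrt(stats::var(a) + stats::var(b))
    num <- mean(a) - mean(b)
    t_obs <- if (den == 0) { if (num == 0) 0 else sign(num) * Inf } else
      num / den
    ac <- a - mean(a)
    bc <- b - mean(b)
    t_null <- if (den == 0) rep(0, n_t_boot) else
      (ac[sample.int(na, n_t_boot, replace = TRUE)] -
         bc[sample.int(nb, n_t_boot, replace = TRUE)]) / den
    p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_t_boot)
    data.frame(L = L_set[j], mean_A = mean(a), mean_B = mean(b),
               t_statistic = t_obs, p_value = p,
               n_resamples = n_resamples,
               columns_per_sample = columns_per_sample)
  })
  do.call(rbind, out)
}
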