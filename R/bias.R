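## ---------------------------------------------------------------------------
## Context bias (rho - 1) * f and per-scale totals
## ---------------------------------------------------------------------------

## number of substituted positions per pattern (N positions never differ)
.n_substitutions <- function(L, anc, desc) {
  out <- rep(0L, length(anc))
  for (j in seq_len(L))
    out <- out + (digit_at(anc, L, j) != digit_at(desc, L, j))
  out
}

## does the ancestral word contain a contiguous CG dinucleotide?
.anc_has_cpg <- function(L, anc) {
  if (L < 2L) return(rep(FALSE, length(anc)))
  out <- rep(FALSE, length(anc))
  for (j in seq_len(L - 1L))
    out <- out | (digit_at(anc, L, j) == 1 & digit_at(anc, L, j + 1L) == 2)
  out
}

#' Per-pattern bias records at one length
#'
#' Computes, for every observed pattern of length `L` (all gap masks), the
#' conversion proportion, frequency, relative abundance and context bias
#' `(rho - 1) * f`.  Unobserved patterns have context bias exactly 0;
#' patterns whose rho is undefined carry `NA` with a reason code.
#'
#' @param table a `pattern_count_table`.
#' @param L pattern length.
#' @param pattern_filter `"all"` (identity and multi-substitution patterns
#'   included), `"substitutions_only"` (ancestor != descendant), or
#'   `"single_substitution"` (exactly one changed position, the reporting
#'   universe of top-pattern tables).
#' @param exclude_ancestral_cpg drop patterns whose ancestral word contains
#'   a contiguous CG (pattern-level CpG removal; window-level removal is an
#'   option of [count_patterns()]).
#' @param method rho algorithm, `"fast"` or `"recursive"`.
#' @return `data.frame` with columns `pattern`, `revcomp`, `L`, `count`,
#'   `pr`, `f`, `rho`, `context_bias`, `reason`, sorted by decreasing
#'   `|context_bias|`.
#' @export
bias_table <- function(table, L,
                       pattern_filter = c("all", "substitutions_only",
                                          "single_substitution"),
                       exclude_ancestral_cpg = FALSE,
                       method = c("fast", "recursive")) {
  pattern_filter <- match.arg(pattern_filter)
  method <- match.arg(method)
  tab <- table$tabs[[as.character(L)]]
  if (is.null(tab) || !nrow(tab))
    stop(sprintf("no windows counted at L=%d", L))
  rows <- data.table(L = L, anc = tab$anc, desc = tab$desc)
  nsub <- .n_substitutions(L, rows$anc, rows$desc)
  keep <- switch(pattern_filter,
                 all = rep(TRUE, nrow(rows)),
                 substitutions_only = nsub > 0L,
                 single_substitution = nsub == 1L)
  if (exclude_ancestral_cpg) keep <- keep & !.anc_has_cpg(L, rows$anc)
  rows <- rows[keep]
  if (!nrow(rows)) stop("no patterns left after filtering")
  res <- rho_table(table, format_patterns(L, rows$anc, rows$desc),
                   method = method)
  res$f <- res$count / (table$windows[[as.character(L)]] * n_gap_masks(L))
  res$context_bias <- ifelse(res$count == 0, 0, (res$rho - 1) * res$f)
  res <- res[order(-abs(res$context_bias)),
             c("pattern", "revcomp", "L", "count", "pr", "f", "rho",
               "context_bias", "reason")]
  rownames(res) <- NULL
  res
}

#' Context bias of one or more patterns
#'
#' `(rho(P) - 1) * f(P)`: the impact of the pattern's over- or
#' under-representation on genome composition, weighting the deviation of
#' rho from 1 by how often the pattern occurs.  Exactly 0 for unobserved
#' patterns; `NA` when rho is undefined for an observed pattern.
#'
#' @inheritParams pattern_proportion
#' @param method rho algorithm.
#' @return Named numeric vector.
#' @export
context_bias <- function(table, patterns, method = c("fast", "recursive")) {
  method <- match.arg(method)
  res <- rho_table(table, patterns, method = method)
  f <- pattern_frequency(table, res$pattern)
  cb <- ifelse(res$count == 0, 0, (res$rho - 1) * f)
  setNames(cb[match(patterns, res$pattern)], patterns)
}

#' Total context bias at one or more scales
#'
#' The cumulative measure of context bias at length `L`: the sum over
#' selected length-L patterns of `|rho - 1| * w`, with `w = f(P)`
#' (frequency weighting) or `1/N` where `N` is the number of selected
#' defined patterns (uniform weighting, used to separate bias differences
#' from pattern-composition differences).  Patterns with undefined rho are
#' skipped and counted; the skip counts are reported in the `"details"`
#' attribute so sums across datasets remain auditable.
#'
#' @inheritParams bias_table
#' @param L integer vector of pattern lengths.
#' @param weighting `"frequency"` or `"uniform"`.
#' @return Named numeric vector (one value per length, `>= 0`), with a
#'   `data.frame` attribute `"details"` (columns `L`, `n_selected`,
#'   `n_defined`, `n_skipped`).
#' @examples
#' tab <- count_patterns(list(alignment_block("CACGCA", "CATGCA")), Lmax = 2)
#' total_context_bias(tab, 2)  # 1.1
#' @export
total_context_bias <- function(table, L,
                               pattern_filter = c("all", "substitutions_only",
                                                  "single_substitution"),
                               weighting = c("frequency", "uniform"),
                               exclude_ancestral_cpg = FALSE,
                               method = c("fast", "recursive")) {
  pattern_filter <- match.arg(pattern_filter)
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  out <- numeric(length(L))
  details <- vector("list", length(L))
  for (i in seq_along(L)) {
    bt <- bias_table(table, L[i], pattern_filter = pattern_filter,
                     exclude_ancestral_cpg = exclude_ancestral_cpg,
                     method = method)
    bt <- bt[bt$count > 0, ]
    defined <- !is.na(bt$rho)
    if (!any(defined)) {
      out[i] <- NA_real_
    } else if (weighting == "frequency") {
      out[i] <- sum(abs(bt$rho[defined] - 1) * bt$f[defined])
    } else {
      out[i] <- mean(abs(bt$rho[defined] - 1))
    }
    details[[i]] <- data.frame(L = L[i], n_selected = nrow(bt),
                               n_defined = sum(defined),
                               n_skipped = sum(!defined))
  }
  structure(setNames(out, as.character(L)),
            details = do.call(rbind, details))
}

#' Rank per-pattern context-bias differences between two datasets
#'
#' For every length-L pattern with a defined context bias in both tables,
#' computes `context_bias_A - context_bias_B`, sorts differences in
#' descending order and attaches the running cumulative sum.  A steep
#' cumulative curve flattening early shows that a small number of patterns
#' drives the difference between the datasets.
#'
#' @param tableA,tableB `pattern_count_table`s.
#' @param L pattern length.
#' @param method rho algorithm.
#' @return `data.frame(pattern, revcomp, context_bias_A, context_bias_B,
#'   difference, cumulative)`, sorted by decreasing difference.
#' @export
rank_pattern_differences <- function(tableA, tableB, L,
                                     method = c("fast", "recursive")) {
  method <- match.arg(method)
  btA <- bias_table(tableA, L, method = method)
  btB <- bias_table(tableB, L, method = method)
  shared <- merge(
    btA[, c("pattern", "revcomp", "context_bias")],
    btB[, c("pattern", "context_bias")],
    by = "pattern", suffixes = c("_A", "_B"))
  shared <- shared[!is.na(shared$context_bias_A) &
                     !is.na(shared$context_bias_B), ]
  if (!nrow(shared)) {
    return(data.frame(pattern = character(0), revcomp = character(0),
                      context_bias_A = numeric(0), context_bias_B = numeric(0),
                      difference = numeric(0), cumulative = numeric(0)))
  }
  shared$difference <- shared$context_bias_A - shared$context_bias_B
  shared <- shared[order(-shared$difference), ]
  shared$cumulative <- cumsum(shared$difference)
  rownames(shared) <- NULL
  shared[, c("pattern", "revcomp", "context_bias_A", "context_bias_B",
             "difference", "cumulative")]
}
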