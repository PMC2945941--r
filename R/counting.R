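## ---------------------------------------------------------------------------
## Pattern and ancestral-word counting over window streams
## ---------------------------------------------------------------------------

## All gap masks of length L as kept-position vectors (ends always kept):
## 2^(L-2) masks for L >= 2, one for L = 1.
.all_masks <- function(L) {
  if (L == 1L) return(list(1L))
  interior <- if (L > 2L) 2:(L - 1L) else integer(0)
  out <- list()
  for (code in 0:(2^length(interior) - 1L)) {
    sel <- interior[bitwAnd(code, 2^(seq_along(interior) - 1L)) > 0L]
    out[[length(out) + 1L]] <- sort(c(1L, sel, L))
  }
  out
}

.mask_string <- function(L, kept) {
  bits <- rep("0", L)
  bits[kept] <- "1"
  paste(bits, collapse = "")
}

## Count one (L, mask) combination over valid window starts.  Codes are
## assembled positionally; masked positions contribute the constant N digit.
## Returns data.table(anc, desc, count).
.count_one_mask <- function(prep, starts, L, kept) {
  if (!length(starts))
    return(data.table(anc = numeric(0), desc = numeric(0), count = numeric(0)))
  nconst <- if (length(kept) < L)
    sum(4 * 5^(L - setdiff(seq_len(L), kept))) else 0
  ca <- rep(nconst, length(starts))
  cd <- rep(nconst, length(starts))
  for (j in kept) {
    w <- 5^(L - j)
    ca <- ca + prep$anc[starts + j - 1L] * w
    cd <- cd + prep$desc[starts + j - 1L] * w
  }
  nbins <- 5^(2L * L)
  if (nbins <= 1e7 && nbins <= 16 * length(starts) + 65536) {
    tab <- tabulate(as.integer(ca * 5^L + cd) + 1L, nbins = nbins)
    nz <- which(tab > 0L)
    comb <- nz - 1
    data.table(anc = comb %/% 5^L, desc = comb %% 5^L,
               count = as.numeric(tab[nz]))
  } else {
    dt <- data.table(anc = ca, desc = cd)
    dt[, list(count = as.numeric(.N)), by = list(anc, desc)]
  }
}

.empty_count_table <- function(Lset, exclude_ancestral_cpg) {
  tabs <- setNames(vector("list", max(Lset)), as.character(seq_len(max(Lset))))
  structure(list(Lmax = max(Lset), Lset = Lset,
                 windows = setNames(numeric(max(Lset)),
                                    as.character(seq_len(max(Lset)))),
                 tabs = tabs, anc_tabs = tabs,
                 exclude_ancestral_cpg = exclude_ancestral_cpg,
                 n_blocks = 0L, n_columns = 0),
            class = "pattern_count_table")
}

.count_from_prep <- function(prep, Lset, exclude_ancestral_cpg = FALSE,
                             masks_by_L = NULL) {
  out <- .empty_count_table(Lset, exclude_ancestral_cpg)
  for (L in Lset) {
    starts <- .window_starts(prep, L, exclude_ancestral_cpg)
    out$windows[[as.character(L)]] <- length(starts)
    masks <- if (is.null(masks_by_L)) .all_masks(L) else masks_by_L[[as.character(L)]]
    parts <- lapply(masks, function(kept) .count_one_mask(prep, starts, L, kept))
    tab <- rbindlist(parts)
    setkeyv(tab, c("anc", "desc"))
    out$tabs[[as.character(L)]] <- tab
    atab <- tab[, list(count = sum(count)), by = anc]
    setkeyv(atab, "anc")
    out$anc_tabs[[as.character(L)]] <- atab
  }
  out
}

#' Count substitution patterns and ancestral words
#'
#' For each window length `L` in `1..Lmax`, every valid window (L
#' consecutive alignment columns, gap-free and N-free in both sequences, not
#' spanning block boundaries) contributes one observation per gap mask of
#' length `L` to both the pattern counts (masked ancestor -> masked
#' descendant) and the ancestral-word counts.  Counting is a single
#' streaming pass; identity and multi-substitution patterns are counted and
#' filtered only downstream.
#'
#' @param blocks an `alignment_blocks` list (or list of `alignment_block`).
#' @param Lmax largest window length (supported to 7; routinely used to 5).
#' @param exclude_ancestral_cpg remove windows touching an ancestral CpG
#'   (see [alignment_windows()]).
#' @return A `pattern_count_table` with per-length sparse count tables,
#'   ancestral-word tables and valid-window counts.
#' @examples
#' b <- alignment_block("CACGCA", "CATGCA")
#' tab <- count_patterns(list(b), Lmax = 2)
#' pattern_proportion(tab, "CG->TG")
#' @export
count_patterns <- function(blocks, Lmax, exclude_ancestral_cpg = FALSE) {
  stopifnot(Lmax >= 1L, Lmax <= 7L)
  if (!length(blocks)) return(.empty_count_table(seq_len(Lmax),
                                                 exclude_ancestral_cpg))
  prep <- .prep_blocks(blocks)
  out <- .count_from_prep(prep, seq_len(Lmax), exclude_ancestral_cpg)
  out$n_blocks <- length(blocks)
  out$n_columns <- sum(vapply(blocks, `[[`, 0, "n_columns"))
  out
}

#' @export
print.pattern_count_table <- function(x, ...) {
  cat(sprintf("<pattern_count_table: Lmax=%d, %d blocks, %s columns%s>\n",
              x$Lmax, x$n_blocks, format(x$n_columns, big.mark = ","),
              if (isTRUE(x$exclude_ancestral_cpg)) ", CpG-excluded" else ""))
  for (L in x$Lset)
    cat(sprintf("  L=%d: %s windows, %d distinct patterns\n", L,
                format(x$windows[[as.character(L)]], big.mark = ","),
                nrow(x$tabs[[as.character(L)]])))
  invisible(x)
}

## Internal vectorised count lookups on parsed pattern rows (L, anc, desc).
.pattern_counts_of <- function(table, pp) {
  out <- numeric(nrow(pp))
  for (L in unique(pp$L)) {
    i <- which(pp$L == L)
    tab <- table$tabs[[as.character(L)]]
    if (is.null(tab)) stop(sprintf("count table has no counts at L=%d", L))
    v <- tab[pp[i, list(anc, desc)], on = c("anc", "desc"), count]
    v[is.na(v)] <- 0
    out[i] <- v
  }
  out
}

.anc_counts_of <- function(table, pp) {
  out <- numeric(nrow(pp))
  for (L in unique(pp$L)) {
    i <- which(pp$L == L)
    atab <- table$anc_tabs[[as.character(L)]]
    if (is.null(atab)) stop(sprintf("count table has no counts at L=%d", L))
    v <- atab[pp[i, list(anc)], on = "anc", count]
    v[is.na(v)] <- 0
    out[i] <- v
  }
  out
}

#' Conversion proportion of a pattern
#'
#' `pr(P)`: the fraction of occurrences of the (possibly gapped) ancestral
#' word that converted to the pattern's descendant word.  Undefined (`NA`)
#' when the ancestral word was never observed; zero-count patterns with an
#' observed ancestor have proportion 0.
#'
#' @param table a `pattern_count_table`.
#' @param patterns character vector of pattern strings `"ANC->DESC"`.
#' @return Named numeric vector of proportions in `[0, 1]`, `NA` where
#'   undefined.
#' @export
pattern_proportion <- function(table, patterns) {
  pp <- parse_patterns(patterns)
  num <- .pattern_counts_of(table, pp)
  den <- .anc_counts_of(table, pp)
  setNames(ifelse(den > 0, num / den, NA_real_), patterns)
}

#' Frequency of a pattern among all same-length patterns
#'
#' `f(P)`: the pattern's count divided by the total count of all gapped and
#' ungapped patterns of the same length, i.e. `windows(L) * 2^(L-2)` (one
#' observation per window per mask).  This is the weight used by the
#' context-bias statistics; frequencies of one length sum to 1.
#'
#' @inheritParams pattern_proportion
#' @return Named numeric vector; `NA` when no windows exist at that length.
#' @export
pattern_frequency <- function(table, patterns) {
  pp <- parse_patterns(patterns)
  num <- .pattern_counts_of(table, pp)
  den <- table$windows[as.character(pp$L)] * n_gap_masks(pp$L)
  setNames(ifelse(den > 0, num / den, NA_real_), patterns)
}

## ---------------------------------------------------------------------------
## TSV serialisation
## ---------------------------------------------------------------------------

#' Write a count table as TSV
#'
#' Columns: `length`, `mask` (bitstring, 1 = kept), `pattern`, `anc_count`,
#' `pattern_count`.  Header comment lines record window counts and options
#' so the table can be reloaded losslessly with [read_count_table()].
#'
#' @param table a `pattern_count_table`.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  writeLines(c(
    "# ctxbias count table v1",
    sprintf("# Lmax=%d", table$Lmax),
    sprintf("# Lset=%s", paste(table$Lset, collapse = ",")),
    sprintf("# windows=%s", paste(sprintf("%d:%.0f", seq_along(table$windows),
                                          table$windows), collapse = ",")),
    sprintf("# exclude_ancestral_cpg=%s", table$exclude_ancestral_cpg),
    sprintf("# n_blocks=%d", table$n_blocks),
    sprintf("# n_columns=%.0f", table$n_columns)), con)
  close(con)
  rows <- rbindlist(lapply(table$Lset, function(L) {
    tab <- table$tabs[[as.character(L)]]
    if (!nrow(tab)) return(NULL)
    atab <- table$anc_tabs[[as.character(L)]]
    anc_count <- atab[tab[, list(anc)], on = "anc", count]
    kept <- lapply(seq_len(L), function(j) digit_at(tab$anc, L, j) != 4)
    mask <- do.call(paste0, lapply(kept, function(k) as.integer(k)))
    data.table(length = L, mask = mask,
               pattern = format_patterns(L, tab$anc, tab$desc),
               anc_count = anc_count, pattern_count = tab$count)
  }))
  data.table::fwrite(rows, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV file.
#' @return A `pattern_count_table`.
#' @export
read_count_table <- function(path) {
  hdr <- readLines(path, n = 16L)
  hdr <- hdr[startsWith(hdr, "# ")]
  getv <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(line)) stop(sprintf("missing '%s' header in %s", key, path))
    sub(paste0("^# ", key, "="), "", line[1L])
  }
  Lset <- as.integer(strsplit(getv("Lset"), ",")[[1L]])
  out <- .empty_count_table(Lset, as.logical(getv("exclude_ancestral_cpg")))
  wspec <- strsplit(strsplit(getv("windows"), ",")[[1L]], ":")
  for (w in wspec) out$windows[[w[1L]]] <- as.numeric(w[2L])
  out$n_blocks <- as.integer(getv("n_blocks"))
  out$n_columns <- as.numeric(getv("n_columns"))
  rows <- data.table::fread(path, sep = "\t", skip = "length\tmask")
  if (nrow(rows)) {
    pp <- parse_patterns(rows$pattern)
    pp[, count := rows$pattern_count]
    for (LL in Lset) {
      tab <- pp[L == LL, list(anc, desc, count)]
      setkeyv(tab, c("anc", "desc"))
      out$tabs[[as.character(LL)]] <- tab
      atab <- tab[, list(count = sum(count)), by = anc]
      setkeyv(atab, "anc")
      out$anc_tabs[[as.character(LL)]] <- atab
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Per-block counting (block bootstrap substrate)
## ---------------------------------------------------------------------------

## Count each block separately for a restricted set of (L, mask) combos.
## lmasks: list of list(L =, kept =).  Returns the additive pieces a
## bootstrap replicate needs: per-block sparse counts, per-block window
## counts per L, per-block column counts.
.blockwise_counts <- function(blocks, lmasks, exclude_ancestral_cpg = FALSE) {
  Lset <- sort(unique(vapply(lmasks, `[[`, 0L, "L")))
  masks_by_L <- setNames(lapply(Lset, function(L) {
    lapply(Filter(function(x) x$L == L, lmasks), `[[`, "kept")
  }), as.character(Lset))
  n_b <- length(blocks)
  counts <- vector("list", n_b)
  windows <- matrix(0, nrow = n_b, ncol = length(Lset),
                    dimnames = list(NULL, as.character(Lset)))
  for (k in seq_len(n_b)) {
    prep <- .prep_blocks(blocks[k])
    parts <- list()
    for (LL in Lset) {
      starts <- .window_starts(prep, LL, exclude_ancestral_cpg)
      windows[k, as.character(LL)] <- length(starts)
      for (kept in masks_by_L[[as.character(LL)]]) {
        one <- .count_one_mask(prep, starts, LL, kept)
        if (nrow(one)) {
          one[, L := ..LL]
          parts[[length(parts) + 1L]] <- one
        }
      }
    }
    if (length(parts)) {
      bk <- rbindlist(parts)
      bk[, block := k]
      counts[[k]] <- bk
    }
  }
  all_counts <- rbindlist(counts)
  bw <- list(counts = all_counts,
             windows = windows,
             columns = vapply(blocks, `[[`, 0, "n_columns"),
             Lset = Lset,
             exclude_ancestral_cpg = exclude_ancestral_cpg)
  ## dense fast path: one block x key matrix per length, so a bootstrap
  ## replicate's counts are a single matrix-vector product
  if (nrow(all_counts)) {
    keys <- unique(all_counts[, list(L, anc, desc)])
    if (n_b * nrow(keys) <= 2e7) {
      dense <- list()
      for (LL in Lset) {
        kk <- keys[L == LL]
        setkeyv(kk, c("anc", "desc"))
        cc <- all_counts[L == LL]
        M <- matrix(0, nrow = n_b, ncol = nrow(kk))
        ki <- kk[cc[, list(anc, desc)], on = c("anc", "desc"), which = TRUE]
        M[cbind(cc$block, ki)] <- cc$count
        dense[[as.character(LL)]] <- list(keys = kk, M = M)
      }
      bw$dense <- dense
    }
  }
  bw
}

## Aggregate blockwise counts for a multiset of block indices into a
## pattern_count_table (counts are additive across blocks).
.aggregate_block_counts <- function(bw, block_idx) {
  w <- tabulate(block_idx, nbins = nrow(bw$windows))
  out <- .empty_count_table(bw$Lset, bw$exclude_ancestral_cpg)
  out$windows[colnames(bw$windows)] <- as.numeric(w %*% bw$windows)
  out$n_blocks <- length(block_idx)
  out$n_columns <- sum(w * bw$columns)
  if (!is.null(bw$dense)) {
    for (LL in bw$Lset) {
      d <- bw$dense[[as.character(LL)]]
      cnt <- as.numeric(w %*% d$M)
      nz <- cnt > 0
      tab <- data.table(anc = d$keys$anc[nz], desc = d$keys$desc[nz],
                        count = cnt[nz])
      setkeyv(tab, c("anc", "desc"))
      out$tabs[[as.character(LL)]] <- tab
      atab <- tab[, list(count = sum(count)), by = anc]
      setkeyv(atab, "anc")
      out$anc_tabs[[as.character(LL)]] <- atab
    }
    return(out)
  }
  dt <- bw$counts
  if (nrow(dt)) {
    wt <- w[dt$block]
    agg <- dt[wt > 0][, list(count = sum(count * w[block])),
                      by = list(L, anc, desc)]
    for (LL in bw$Lset) {
      tab <- agg[L == LL, list(anc, desc, count)]
      setkeyv(tab, c("anc", "desc"))
      out$tabs[[as.character(LL)]] <- tab
      atab <- tab[, list(count = sum(count)), by = anc]
      setkeyv(atab, "anc")
      out$anc_tabs[[as.character(LL)]] <- atab
    }
  }
  out
}
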