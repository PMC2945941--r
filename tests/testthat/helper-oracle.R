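# Independent brute-force oracle: direct string manipulation, no shared code
# with the package internals.  Deliberately naive; use on tiny inputs only.

oracle_windows <- function(block, L) {
  a <- strsplit(block$ancestor, "")[[1L]]
  d <- strsplit(block$descendant, "")[[1L]]
  good <- a %in% c("A", "C", "G", "T") & d %in% c("A", "C", "G", "T")
  out <- list()
  if (length(a) < L) return(out)
  for (i in seq_len(length(a) - L + 1L)) {
    if (all(good[i:(i + L - 1L)])) {
      out[[length(out) + 1L]] <- c(
        paste(a[i:(i + L - 1L)], collapse = ""),
        paste(d[i:(i + L - 1L)], collapse = ""))
    }
  }
  out
}

oracle_pr <- function(blocks, pattern) {
  halves <- strsplit(pattern, "->", fixed = TRUE)[[1L]]
  pa <- strsplit(halves[1L], "")[[1L]]
  pd <- strsplit(halves[2L], "")[[1L]]
  L <- length(pa)
  n_anc <- 0L
  n_pat <- 0L
  for (b in blocks) {
    for (w in oracle_windows(b, L)) {
      wa <- strsplit(w[1L], "")[[1L]]
      wd <- strsplit(w[2L], "")[[1L]]
      if (all(pa == "N" | pa == wa)) {
        n_anc <- n_anc + 1L
        if (all(pa == "N" | pd == wd)) n_pat <- n_pat + 1L
      }
    }
  }
  if (n_anc == 0L) NA_real_ else n_pat / n_anc
}

# all proper non-empty position subsets of the non-N positions, re-spanned,
# as pattern strings (with multiplicity: one entry per subset)
oracle_subpattern_list <- function(pattern) {
  halves <- strsplit(pattern, "->", fixed = TRUE)[[1L]]
  pa <- strsplit(halves[1L], "")[[1L]]
  pd <- strsplit(halves[2L], "")[[1L]]
  kept <- which(pa != "N")
  out <- character(0)
  for (k in seq_len(length(kept) - 1L)) {
    sets <- utils::combn(kept, k, simplify = FALSE)
    for (s in sets) {
      span <- min(s):max(s)
      sa <- ifelse(span %in% s, pa[span], "N")
      sd <- ifelse(span %in% s, pd[span], "N")
      out <- c(out, paste0(paste(sa, collapse = ""), "->",
                           paste(sd, collapse = "")))
    }
  }
  out
}

oracle_rho <- function(blocks, pattern, memo = new.env(parent = emptyenv())) {
  hit <- memo[[pattern]]
  if (!is.null(hit)) return(hit)
  pr <- oracle_pr(blocks, pattern)
  subs <- oracle_subpattern_list(pattern)
  val <- if (!length(subs)) {
    pr
  } else {
    psi <- 1
    bad <- FALSE
    for (s in subs) {
      r <- oracle_rho(blocks, s, memo)
      if (is.na(r)) { bad <- TRUE; break }
      psi <- psi * r
    }
    if (bad || is.na(pr) || psi == 0) NA_real_ else pr / psi
  }
  assign(pattern, val, envir = memo)
  val
}

# every observed pattern of length L over all gap masks, by direct scan
oracle_observed_patterns <- function(blocks, L) {
  masks <- list()
  interior <- if (L > 2L) 2:(L - 1L) else integer(0)
  for (code in 0:(2^length(interior) - 1L)) {
    sel <- interior[bitwAnd(code, 2^(seq_along(interior) - 1L)) > 0L]
    masks[[length(masks) + 1L]] <- sort(c(1L, sel, if (L > 1L) L))
  }
  pats <- character(0)
  counts <- integer(0)
  for (b in blocks) {
    for (w in oracle_windows(b, L)) {
      wa <- strsplit(w[1L], "")[[1L]]
      wd <- strsplit(w[2L], "")[[1L]]
      for (kept in masks) {
        sa <- ifelse(seq_len(L) %in% kept, wa, "N")
        sd <- ifelse(seq_len(L) %in% kept, wd, "N")
        p <- paste0(paste(sa, collapse = ""), "->", paste(sd, collapse = ""))
        j <- match(p, pats)
        if (is.na(j)) { pats <- c(pats, p); counts <- c(counts, 1L) }
        else counts[j] <- counts[j] + 1L
      }
    }
  }
  data.frame(pattern = pats, count = counts, stringsAsFactors = FALSE)
}

oracle_total_bias <- function(blocks, L) {
  obs <- oracle_observed_patterns(blocks, L)
  n_windows <- sum(vapply(blocks, function(b) length(oracle_windows(b, L)), 0L))
  n_masks <- if (L >= 2L) 2^(L - 2L) else 1L
  memo <- new.env(parent = emptyenv())
  total <- 0
  for (i in seq_len(nrow(obs))) {
    r <- oracle_rho(blocks, obs$pattern[i], memo)
    if (is.na(r)) next
    total <- total + abs(r - 1) * obs$count[i] / (n_windows * n_masks)
  }
  total
}

# brute-force BH step-up straight from the definition:
# q_(i) = min(1, min over j >= i of p_(j) * m / j), in original order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- qs
  q
}
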