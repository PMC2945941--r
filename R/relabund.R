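## ---------------------------------------------------------------------------
## Relative abundance: recursive definition and fast algorithm
##
## rho(P) = pr(P)                         L = 1
##        = pr(P) / psi(P)                L > 1 (recursive definition)
## with psi(P) the product of rho over the subpattern set S_P.  The fast
## algorithm rewrites the L > 2 case as
##   pr(P) * pr(B2..B_{L-1}) / (pr(B1..B_{L-1}) * pr(B2..B_L) * gamma(P))
## with gamma the product of rho over the full-length gapped subpatterns
## G_P; interior substrings are trimmed of flanking N before the pr lookup
## (an all-N substring contributes a factor of 1).  The two routes are
## algebraically equivalent; the recursive definition is normative.
##
## Undefined values propagate as NA and are never coerced to 0 or 1: rho is
## undefined when pr is undefined (ancestral word unseen), when any
## subpattern's rho is undefined, or when a zero lands in a denominator.
## ---------------------------------------------------------------------------

## Parsed rows (L, anc, desc) -> all subpattern rows (union of S_P).
.sub_rows <- function(rows) {
  parts <- list()
  rows <- as.data.table(rows)
  rows[, mb := mask_bits(anc, L[1L]), by = L]
  for (grp in split(rows, by = c("L", "mb"))) {
    L <- grp$L[1L]
    if (L == 1L) next
    kept <- which(digit_at(grp$anc[1L], L, seq_len(L)) != 4)
    info <- mask_info(L, kept)
    adig <- ddig <- vector("list", L)
    for (j in kept) {
      adig[[j]] <- digit_at(grp$anc, L, j)
      ddig[[j]] <- digit_at(grp$desc, L, j)
    }
    for (d in info$subsets) {
      parts[[length(parts) + 1L]] <- data.table(
        L = d$subL,
        anc = .apply_descriptor(d, adig),
        desc = .apply_descriptor(d, ddig))
    }
  }
  if (!length(parts)) return(NULL)
  unique(rbindlist(parts))
}

## Core engine: compute pr, rho (both routes) for a set of parsed pattern
## rows, levelwise in the number of non-N positions so every subpattern is
## ready before its parents.
.rho_engine <- function(table, req) {
  req <- unique(as.data.table(req)[, list(L, anc, desc)])
  subs <- .sub_rows(req)
  all_rows <- unique(rbindlist(list(req, subs)))
  num <- .pattern_counts_of(table, all_rows)
  den <- .anc_counts_of(table, all_rows)
  all_rows[, count := num]
  all_rows[, pr := ifelse(den > 0, num / den, NA_real_)]
  all_rows[, mb := mask_bits(anc, L[1L]), by = L]
  all_rows[, m := {
    LL <- L[1L]
    nn <- rep(0L, .N)
    for (j in seq_len(LL)) nn <- nn + (digit_at(anc, LL, j) != 4L)
    nn
  }, by = L]

  ## computed patterns are addressed by a packed numeric key (exact for
  ## L <= 7); lookups are single match() calls per group and level
  P7 <- 5^7
  keyof <- function(L, anc, desc) (L * P7 + anc) * P7 + desc
  all_rows[, key := keyof(L, anc, desc)]

  acc_key <- numeric(0)
  acc_pr <- numeric(0)
  acc_rec <- numeric(0)
  acc_fast <- numeric(0)
  out_parts <- list()
  for (lvl in sort(unique(all_rows$m))) {
    lvl_rows <- all_rows[m == lvl]
    done <- list()
    for (grp in split(lvl_rows, by = c("L", "mb"))) {
      L <- grp$L[1L]
      n <- nrow(grp)
      if (lvl == 1L) {
        grp[, rho_rec := pr]
        grp[, rho_fast := pr]
        grp[, reason_rec := ifelse(is.na(pr), "pr_undefined", "ok")]
        grp[, reason_fast := reason_rec]
        done[[length(done) + 1L]] <- grp
        next
      }
      kept <- which(digit_at(grp$anc[1L], L, seq_len(L)) != 4)
      info <- mask_info(L, kept)
      adig <- ddig <- vector("list", L)
      for (j in kept) {
        adig[[j]] <- digit_at(grp$anc, L, j)
        ddig[[j]] <- digit_at(grp$desc, L, j)
      }
      S <- length(info$subsets)
      sub_keys <- vector("list", S)
      for (s in seq_len(S)) {
        d <- info$subsets[[s]]
        sub_keys[[s]] <- keyof(d$subL, .apply_descriptor(d, adig),
                               .apply_descriptor(d, ddig))
      }
      idx <- match(unlist(sub_keys, use.names = FALSE), acc_key)
      idx <- matrix(idx, nrow = n, ncol = S)
      rec_m <- matrix(acc_rec[idx], nrow = n, ncol = S)
      psi_v <- rep(1, n)
      sub_na <- rep(FALSE, n)
      for (s in seq_len(S)) {
        v <- rec_m[, s]
        nav <- is.na(v)
        sub_na <- sub_na | nav
        v[nav] <- 1
        psi_v <- psi_v * v
      }
      grp[, rho_rec := ifelse(is.na(pr) | sub_na | psi_v == 0,
                              NA_real_, pr / psi_v)]
      grp[, reason_rec := ifelse(is.na(pr), "pr_undefined",
                          ifelse(sub_na, "subpattern_undefined",
                          ifelse(psi_v == 0, "zero_subpattern", "ok")))]
      if (L <= 2L) {
        ## for L = 2 the fast route coincides with the recursive one
        grp[, rho_fast := rho_rec]
        grp[, reason_fast := reason_rec]
      } else {
        fast_m <- matrix(acc_fast[idx], nrow = n, ncol = S)
        gamma <- rep(1, n)
        g_na <- rep(FALSE, n)
        for (s in info$gp_idx) {
          v <- fast_m[, s]
          nav <- is.na(v)
          g_na <- g_na | nav
          v[nav] <- 1
          gamma <- gamma * v
        }
        pr_m <- matrix(acc_pr[idx], nrow = n, ncol = S)
        term <- function(i) if (i == 0L) rep(1, n) else pr_m[, i]
        pr_mid <- term(info$mid_idx)
        pr_left <- term(info$left_idx)
        pr_right <- term(info$right_idx)
        den <- pr_left * pr_right * gamma
        any_na <- is.na(pr_mid) | is.na(pr_left) | is.na(pr_right) | g_na
        grp[, rho_fast := ifelse(is.na(pr) | any_na | den == 0,
                                 NA_real_, pr * pr_mid / den)]
        grp[, reason_fast := ifelse(is.na(pr), "pr_undefined",
                             ifelse(any_na, "subpattern_undefined",
                             ifelse(den == 0, "zero_denominator", "ok")))]
      }
      done[[length(done) + 1L]] <- grp
    }
    lvl_done <- rbindlist(done, use.names = TRUE)
    acc_key <- c(acc_key, lvl_done$key)
    acc_pr <- c(acc_pr, lvl_done$pr)
    acc_rec <- c(acc_rec, lvl_done$rho_rec)
    acc_fast <- c(acc_fast, lvl_done$rho_fast)
    out_parts[[length(out_parts) + 1L]] <- lvl_done
  }
  acc <- rbindlist(out_parts, use.names = TRUE)
  setkeyv(acc, c("L", "anc", "desc"))
  acc[req, on = c("L", "anc", "desc")]
}

#' Relative abundance of substitution patterns
#'
#' Computes pr and rho for the requested patterns (default: every pattern
#' observed in the table), by the recursive definition, the fast
#' full-length-gapped-subpattern algorithm, or both.  The two methods agree
#' wherever both are defined; the recursive definition is normative.
#' Undefined values are `NA` with a machine-readable `reason` column
#' (`pr_undefined`, `subpattern_undefined`, `zero_subpattern`,
#' `zero_denominator`).
#'
#' @param table a `pattern_count_table`.
#' @param patterns character vector of pattern strings, or `NULL` for all
#'   observed patterns.
#' @param method `"fast"`, `"recursive"` or `"both"`.
#' @return A `data.frame` with columns `pattern`, `revcomp`, `L`, `count`,
#'   `pr`, and `rho`/`reason` (or `rho_recursive`, `rho_fast`,
#'   `reason_recursive`, `reason_fast` for `"both"`).
#' @examples
#' tab <- count_patterns(list(alignment_block("CACGCA", "CATGCA")), Lmax = 3)
#' rho_table(tab, c("CG->TG", "CNC->TNC"))
#' @export
rho_table <- function(table, patterns = NULL,
                      method = c("fast", "recursive", "both")) {
  method <- match.arg(method)
  if (is.null(patterns)) {
    req <- rbindlist(lapply(table$Lset, function(L) {
      tab <- table$tabs[[as.character(L)]]
      if (!nrow(tab)) return(NULL)
      data.table(L = L, anc = tab$anc, desc = tab$desc)
    }))
    if (is.null(req) || !nrow(req)) stop("count table is empty")
  } else {
    req <- parse_patterns(patterns)[, list(L, anc, desc)]
  }
  res <- .rho_engine(table, req)
  res[, pattern := character(.N)]
  res[, revcomp := character(.N)]
  res[, c("pattern", "revcomp") := {
    LL <- L[1L]
    list(format_patterns(LL, anc, desc),
         format_patterns(LL, revcomp_code(anc, LL), revcomp_code(desc, LL)))
  }, by = L]
  cols <- c("pattern", "revcomp", "L", "count", "pr")
  out <- switch(method,
    fast = {
      o <- res[, c(cols, "rho_fast", "reason_fast"), with = FALSE]
      data.table::setnames(o, c("rho_fast", "reason_fast"), c("rho", "reason"))
      o
    },
    recursive = {
      o <- res[, c(cols, "rho_rec", "reason_rec"), with = FALSE]
      data.table::setnames(o, c("rho_rec", "reason_rec"), c("rho", "reason"))
      o
    },
    both = {
      o <- res[, c(cols, "rho_rec", "rho_fast",
                   "reason_rec", "reason_fast"), with = FALSE]
      data.table::setnames(o, c("rho_rec", "reason_rec"),
                           c("rho_recursive", "reason_recursive"))
      o
    })
  data.table::setDF(out)
  out
}

#' Relative abundance of one or more patterns
#'
#' @inheritParams rho_table
#' @param patterns character vector of pattern strings.
#' @return Named numeric vector of rho values (`NA` where undefined).
#' @examples
#' tab <- count_patterns(list(alignment_block("CACGCA", "CATGCA")), Lmax = 2)
#' rho(tab, "CG->TG")  # 3
#' @export
rho <- function(table, patterns, method = c("fast", "recursive")) {
  method <- match.arg(method)
  res <- rho_table(table, patterns, method = method)
  setNames(res$rho[match(patterns, res$pattern)], patterns)
}

#' Expected proportion psi of a pattern
#'
#' The product of the relative abundances of the pattern's subpatterns --
#' the denominator of the recursive relative-abundance definition.  The
#' product runs over position subsets, so a subpattern arising from several
#' subsets contributes one factor per subset (`psi(AA->AA) = rho(A->A)^2`);
#' this multiplicity is what makes rho converge to 1 for context-free data.
#' `NA` when any factor is undefined.
#'
#' @inheritParams rho
#' @param pattern a single pattern string of length >= 2.
#' @return Numeric scalar (or `NA`).
#' @export
psi <- function(table, pattern) {
  stopifnot(length(pattern) == 1L)
  plan <- .compile_rho_plan(pattern)
  if (plan$m[plan$req_idx] == 1L)
    stop("psi is defined for patterns of length >= 2")
  ev <- .eval_rho_plan(plan, table)
  sv <- ev$rho_all[plan$sub_idx[[plan$req_idx]]]
  if (anyNA(sv)) return(NA_real_)
  prod(sv)
}
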