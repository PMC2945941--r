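#' @importFrom data.table data.table setkey setkeyv rbindlist setorder as.data.table :=
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Internal encoding
##
## Words over {A,C,G,T,N} are encoded as base-5 integers (stored as doubles):
## A=0, C=1, G=2, T=3, N=4, big-endian so that the first base is the most
## significant digit.  A substitution pattern is a pair (anc, desc) of codes
## of equal length L; the gap mask is implicit in which digits equal 4.
## Codes stay exactly representable as doubles up to L = 7 (5^14 < 2^53).
## ---------------------------------------------------------------------------

.ctx_env <- new.env(parent = emptyenv())

.base_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut[utf8ToInt("N")] <- 4L; lut[utf8ToInt("n")] <- 4L
  lut[utf8ToInt("-")] <- 5L
  lut
})

.BASES <- c("A", "C", "G", "T", "N")

seq_to_ints <- function(x) {
  codes <- utf8ToInt(x)
  if (any(codes > 127L)) stop("non-ASCII character in sequence")
  out <- .base_lut[codes]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("illegal character '%s' at offset %d",
                 substr(x, bad, bad), bad))
  }
  out
}

word_to_code <- function(word) {
  d <- seq_to_ints(word)
  if (any(d > 4L)) stop("gap character not allowed in a pattern word")
  sum(d * 5^(rev(seq_along(d)) - 1L))
}

## digits of a code vector at position j of an L-word (1-based from the left)
digit_at <- function(code, L, j) (code %/% 5^(L - j)) %% 5

code_to_word <- function(code, L) {
  cols <- vector("list", L)
  for (j in seq_len(L)) cols[[j]] <- .BASES[digit_at(code, L, j) + 1]
  do.call(paste0, cols)
}

## reverse complement on codes (vectorised): A<->T, C<->G, N->N, reversed
revcomp_code <- function(code, L) {
  out <- numeric(length(code))
  for (j in seq_len(L)) {
    d <- digit_at(code, L, j)
    out <- out + ifelse(d == 4, 4, 3 - d) * 5^(j - 1L)
  }
  out
}

format_patterns <- function(L, anc, desc) {
  paste0(code_to_word(anc, L), "->", code_to_word(desc, L))
}

## Parse "ANC->DESC" strings into a data.table(pattern, L, anc, desc).
## Enforces the pattern invariants: equal lengths, ends non-N, N positions
## matching between the ancestral and descendant words.
parse_patterns <- function(patterns) {
  halves <- strsplit(patterns, "->", fixed = TRUE)
  bad <- lengths(halves) != 2L
  if (any(bad)) stop(sprintf("malformed pattern '%s'", patterns[which(bad)[1L]]))
  aw <- vapply(halves, `[[`, "", 1L)
  dw <- vapply(halves, `[[`, "", 2L)
  if (any(nchar(aw) != nchar(dw)))
    stop("ancestral and descendant words differ in length")
  L <- nchar(aw)
  anc <- vapply(aw, word_to_code, 0, USE.NAMES = FALSE)
  desc <- vapply(dw, word_to_code, 0, USE.NAMES = FALSE)
  for (i in seq_along(patterns)) {
    da <- digit_at(anc[i], L[i], seq_len(L[i]))
    dd <- digit_at(desc[i], L[i], seq_len(L[i]))
    if (da[1L] == 4 || da[L[i]] == 4)
      stop(sprintf("pattern '%s': first and last ancestral bases must not be N",
                   patterns[i]))
    if (any((da == 4) != (dd == 4)))
      stop(sprintf("pattern '%s': N positions must match in both words",
                   patterns[i]))
  }
  data.table(pattern = patterns, L = as.integer(L), anc = anc, desc = desc)
}

## mask bits of an anc code: bit (L-j) set iff position j is non-N
mask_bits <- function(anc, L) {
  bits <- 0
  for (j in seq_len(L)) bits <- bits + (digit_at(anc, L, j) != 4) * 2^(L - j)
  bits
}

n_gap_masks <- function(L) as.integer(2^pmax(L - 2L, 0L))

## ---------------------------------------------------------------------------
## Mask descriptors
##
## For a pattern of length L whose non-N (kept) positions are `kept`, the
## subpattern set S_P is indexed by the proper non-empty subsets of `kept`:
## each subset spans from its minimum to its maximum position, with
## unselected interior positions set to N.  A descriptor precomputes, for one
## subset, the weights needed to assemble the subpattern code from the parent
## digits, so generation is vectorised over all patterns sharing a mask.
## ---------------------------------------------------------------------------

.subset_descriptor <- function(sel, a, b) {
  subL <- b - a + 1L
  span <- a:b
  wts <- 5^(subL - (sel - a + 1L))
  nmask <- setdiff(span, sel)
  nconst <- if (length(nmask)) sum(4 * 5^(subL - (nmask - a + 1L))) else 0
  list(subL = as.integer(subL), sel = sel, wts = wts, nconst = nconst)
}

## All proper non-empty subsets of kept positions (S_P machinery), plus the
## indices of full-span subsets (G_P, used by the fast algorithm) and the
## trimmed mid/left/right substring descriptors of the fast algorithm.
mask_info <- function(L, kept) {
  key <- paste0("mi:", L, ":", paste(kept, collapse = ","))
  hit <- .ctx_env[[key]]
  if (!is.null(hit)) return(hit)
  m <- length(kept)
  subsets <- list()
  fullspan <- logical(0)
  if (m >= 2L) {
    for (code in seq_len(2^m - 2L)) {         # proper non-empty subsets
      sel <- kept[bitwAnd(code, 2^(seq_len(m) - 1L)) > 0L]
      a <- min(sel); b <- max(sel)
      subsets[[length(subsets) + 1L]] <- .subset_descriptor(sel, a, b)
      fullspan <- c(fullspan, a == 1L && b == L)
    }
  }
  trim_desc <- function(lo, hi) {
    K <- kept[kept >= lo & kept <= hi]
    if (!length(K)) return(NULL)              # all-N substring: pr == 1
    .subset_descriptor(K, min(K), max(K))
  }
  ## index of a trimmed-substring descriptor within `subsets` (0: all-N,
  ## so the pr term is the constant 1)
  find_idx <- function(d) {
    if (is.null(d)) return(0L)
    for (i in seq_along(subsets))
      if (identical(subsets[[i]]$sel, d$sel)) return(i)
    stop("internal: trimmed substring not in subpattern set")
  }
  info <- list(
    L = L, kept = kept, m = m,
    subsets = subsets,
    gp_idx = which(fullspan),
    mid = if (L >= 3L) trim_desc(2L, L - 1L) else NULL,
    left = if (L >= 3L) trim_desc(1L, L - 1L) else NULL,
    right = if (L >= 3L) trim_desc(2L, L) else NULL
  )
  info$mid_idx <- if (L >= 3L) find_idx(info$mid) else 0L
  info$left_idx <- if (L >= 3L) find_idx(info$left) else 0L
  info$right_idx <- if (L >= 3L) find_idx(info$right) else 0L
  assign(key, info, envir = .ctx_env)
  info
}

## Assemble subpattern codes for one descriptor from parent digit columns.
## digits: list over positions 1..L of digit vectors (only kept positions
## are ever referenced).
.apply_descriptor <- function(desc, digits) {
  out <- rep(desc$nconst, length(digits[[desc$sel[1L]]]))
  for (k in seq_along(desc$sel)) out <- out + digits[[desc$sel[k]]] * desc$wts[k]
  out
}

## ---------------------------------------------------------------------------
## Exported pattern algebra
## ---------------------------------------------------------------------------

#' Mask positions of an aligned word pair, producing a gapped pattern
#'
#' Positions with `kept = FALSE` are replaced by `N` in both the ancestral
#' and descendant word, yielding a gapped substitution pattern.  The first
#' and last positions must be kept: pattern ends are non-N by definition.
#'
#' @param ancestral_word,descendant_word equal-length words over `A,C,G,T`.
#' @param kept logical vector of length `nchar(ancestral_word)`, or an
#'   integer vector of positions to keep.
#' @return A pattern string `"ANC->DESC"`.
#' @examples
#' apply_mask("ACT", "ATT", c(1, 3))  # "ANT->ANT"
#' @export
apply_mask <- function(ancestral_word, descendant_word, kept) {
  L <- nchar(ancestral_word)
  if (nchar(descendant_word) != L)
    stop("ancestral and descendant words differ in length")
  if (!is.logical(kept)) kept <- seq_len(L) %in% kept
  if (length(kept) != L) stop("mask length must equal word length")
  if (!kept[1L] || !kept[L]) stop("first and last positions must be kept")
  aw <- strsplit(toupper(ancestral_word), "")[[1L]]
  dw <- strsplit(toupper(descendant_word), "")[[1L]]
  if (any(!aw %in% c("A", "C", "G", "T")) || any(!dw %in% c("A", "C", "G", "T")))
    stop("words must be N-free and gap-free")
  aw[!kept] <- "N"
  dw[!kept] <- "N"
  paste0(paste(aw, collapse = ""), "->", paste(dw, collapse = ""))
}

#' Subpattern set of a substitution pattern
#'
#' Returns `S_P`: for every proper non-empty subset of the pattern's non-N
#' positions, the pattern spanning from the subset's minimum to maximum
#' position, with unselected interior positions set to N.  The relative
#' abundance of a pattern is its conversion proportion divided by the
#' product of the relative abundances of all these constituents.
#'
#' @param pattern pattern string `"ANC->DESC"` (N marks gapped positions).
#' @return Character vector of pattern strings (unique, sorted); empty for
#'   length-1 patterns.
#' @examples
#' subpatterns("ACT->ATT")
#' subpatterns("ANT->ANT")
#' @export
subpatterns <- function(pattern) {
  p <- parse_patterns(pattern)
  if (p$L == 1L) return(character(0))
  kept <- which(digit_at(p$anc, p$L, seq_len(p$L)) != 4)
  info <- mask_info(p$L, kept)
  adig <- lapply(seq_len(p$L), function(j) digit_at(p$anc, p$L, j))
  ddig <- lapply(seq_len(p$L), function(j) digit_at(p$desc, p$L, j))
  out <- vapply(info$subsets, function(d) {
    format_patterns(d$subL, .apply_descriptor(d, adig), .apply_descriptor(d, ddig))
  }, "")
  sort(unique(out))
}

#' Full-length gapped subpatterns
#'
#' Returns `G_P`: every pattern obtained from `P` by masking a non-empty
#' subset of its interior non-N positions, keeping both ends and the full
#' length.  These are the correction terms of the fast relative-abundance
#' algorithm.
#'
#' @inheritParams subpatterns
#' @return Character vector of pattern strings; empty when `L < 3` or the
#'   pattern has no interior non-N positions.
#' @examples
#' full_length_gapped_subpatterns("ACGT->ACGT")
#' @export
full_length_gapped_subpatterns <- function(pattern) {
  p <- parse_patterns(pattern)
  if (p$L < 3L) return(character(0))
  kept <- which(digit_at(p$anc, p$L, seq_len(p$L)) != 4)
  info <- mask_info(p$L, kept)
  if (!length(info$gp_idx)) return(character(0))
  adig <- lapply(seq_len(p$L), function(j) digit_at(p$anc, p$L, j))
  ddig <- lapply(seq_len(p$L), function(j) digit_at(p$desc, p$L, j))
  out <- vapply(info$subsets[info$gp_idx], function(d) {
    format_patterns(d$subL, .apply_descriptor(d, adig), .apply_descriptor(d, ddig))
  }, "")
  sort(unique(out))
}

#' Reverse complement of a substitution pattern
#'
#' Both words are reverse-complemented (N maps to N).  Applying the function
#' twice returns the original pattern.  Counting is performed on the given
#' strand; the reverse-complement label is reported alongside each pattern
#' in output tables, as is conventional for strand-symmetric processes such
#' as CpG deamination (CG->TG is CG->CA on the other strand).
#'
#' @inheritParams subpatterns
#' @return Pattern string.
#' @examples
#' reverse_complement_pattern("CG->TG")   # "CG->CA"
#' reverse_complement_pattern("TNG->CNG") # "CNA->CNG"
#' @export
reverse_complement_pattern <- function(pattern) {
  p <- parse_patterns(pattern)
  out <- character(nrow(p))
  for (L in unique(p$L)) {
    i <- which(p$L == L)
    out[i] <- format_patterns(L, revcomp_code(p$anc[i], L),
                              revcomp_code(p$desc[i], L))
  }
  out
}
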