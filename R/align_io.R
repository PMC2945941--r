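## ---------------------------------------------------------------------------
## Alignment blocks: reading, validation, filtering, windowing
## ---------------------------------------------------------------------------

#' Construct an ancestor-descendant alignment block
#'
#' A block is one contiguous pair of aligned sequences over `A,C,G,T,N,-`
#' (case-insensitive; soft-masked lowercase is uppercased).  Blocks are the
#' resampling unit of the block bootstrap.  Columns gapped in both sequences
#' carry no information and are dropped at construction time; the number
#' dropped is recorded in attribute `"dropped_columns"`.
#'
#' @param ancestor,descendant aligned sequences of identical length.
#' @param block_id identifier used in error messages and outputs.
#' @param source_coords optional list `(name, start, end, strand)` giving the
#'   ancestor's source coordinates (0-based half-open, as in MAF).
#' @return An object of class `alignment_block` with fields `block_id`,
#'   `ancestor`, `descendant`, `n_columns`, `source_coords`.
#' @export
alignment_block <- function(ancestor, descendant, block_id = "block",
                            source_coords = NULL) {
  ancestor <- toupper(ancestor)
  descendant <- toupper(descendant)
  if (nchar(ancestor) != nchar(descendant))
    stop(sprintf("block %s: ancestor (%d) and descendant (%d) lengths differ",
                 block_id, nchar(ancestor), nchar(descendant)))
  ai <- tryCatch(seq_to_ints(ancestor), error = function(e)
    stop(sprintf("block %s, ancestor: %s", block_id, conditionMessage(e)),
         call. = FALSE))
  di <- tryCatch(seq_to_ints(descendant), error = function(e)
    stop(sprintf("block %s, descendant: %s", block_id, conditionMessage(e)),
         call. = FALSE))
  both_gap <- ai == 5L & di == 5L
  dropped <- sum(both_gap)
  if (dropped > 0L) {
    keep <- !both_gap
    ancestor <- paste(strsplit(ancestor, "")[[1L]][keep], collapse = "")
    descendant <- paste(strsplit(descendant, "")[[1L]][keep], collapse = "")
  }
  out <- structure(
    list(block_id = block_id, ancestor = ancestor, descendant = descendant,
         n_columns = nchar(ancestor), source_coords = source_coords),
    class = "alignment_block")
  attr(out, "dropped_columns") <- dropped
  out
}

.as_blocks <- function(lst, skipped = 0L, dropped = 0L) {
  structure(lst, class = "alignment_blocks",
            skipped = skipped, dropped_columns = dropped)
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block %s: %d columns>\n", x$block_id, x$n_columns))
  invisible(x)
}

#' @export
print.alignment_blocks <- function(x, ...) {
  cat(sprintf("<alignment_blocks: %d blocks, %s columns>\n", length(x),
              format(sum(vapply(x, `[[`, 0, "n_columns")), big.mark = ",")))
  invisible(x)
}

#' Read ancestor-descendant alignment blocks
#'
#' Supports two dialects: MAF (standard multiple alignment format; the two
#' species are selected by source-name prefix, the part before the first
#' `.`), and paired aligned FASTA in which records strictly alternate
#' ancestor, descendant and `-` is the only gap character.  Sequences are
#' uppercased and validated; a malformed record (unequal lengths, illegal
#' character) is a hard error naming the block and offset.  MAF blocks
#' lacking either label are skipped; the count is stored in attribute
#' `"skipped"` and reported with a message.
#'
#' @param path input file.
#' @param format `"maf"` or `"paired_fasta"`.
#' @param ancestor_label,descendant_label species prefixes (MAF only).
#' @return An `alignment_blocks` list, in file order.
#' @export
read_alignment_blocks <- function(path,
                                  format = c("paired_fasta", "maf"),
                                  ancestor_label = NULL,
                                  descendant_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "paired_fasta") .read_paired_fasta(path)
  else .read_maf(path, ancestor_label, descendant_label)
}

.read_paired_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) %% 2L != 0L)
    stop("paired FASTA must contain an even number of records")
  ids <- names(recs)
  seqs <- unname(as.character(recs))
  blocks <- vector("list", length(recs) %/% 2L)
  dropped <- 0L
  for (k in seq_along(blocks)) {
    i <- 2L * k - 1L
    bid <- sub("\\s.*$", "", ids[i])
    b <- alignment_block(seqs[i], seqs[i + 1L], block_id = bid)
    dropped <- dropped + attr(b, "dropped_columns")
    blocks[[k]] <- b
  }
  if (dropped > 0L)
    message(sprintf("dropped %d columns gapped in both sequences", dropped))
  .as_blocks(blocks, skipped = 0L, dropped = dropped)
}

.read_maf <- function(path, ancestor_label, descendant_label) {
  if (is.null(ancestor_label) || is.null(descendant_label))
    stop("MAF input requires ancestor_label and descendant_label")
  lines <- readLines(path)
  a_idx <- grep("^a( |$)", lines)
  if (!length(a_idx)) stop("no alignment blocks found in MAF file")
  bounds <- c(a_idx, length(lines) + 1L)
  blocks <- list()
  skipped <- 0L
  dropped <- 0L
  for (k in seq_along(a_idx)) {
    chunk <- lines[a_idx[k]:(bounds[k + 1L] - 1L)]
    s_lines <- grep("^s ", chunk, value = TRUE)
    if (!length(s_lines)) { skipped <- skipped + 1L; next }
    fields <- lapply(s_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
    ok <- vapply(fields, length, 0L) >= 7L
    if (any(!ok)) stop(sprintf("malformed s line in MAF block %d", k))
    src <- vapply(fields, `[[`, "", 2L)
    prefix <- sub("\\..*$", "", src)
    ai <- match(ancestor_label, prefix)
    di <- match(descendant_label, prefix)
    if (is.na(ai) || is.na(di)) { skipped <- skipped + 1L; next }
    fa <- fields[[ai]]
    b <- alignment_block(
      fa[7L], fields[[di]][7L], block_id = sprintf("maf_%d", k),
      source_coords = list(name = fa[2L], start = as.numeric(fa[3L]),
                           end = as.numeric(fa[3L]) + as.numeric(fa[4L]),
                           strand = fa[6L]))
    dropped <- dropped + attr(b, "dropped_columns")
    blocks[[length(blocks) + 1L]] <- b
  }
  if (skipped > 0L)
    message(sprintf("skipped %d MAF blocks lacking both labels", skipped))
  if (dropped > 0L)
    message(sprintf("dropped %d columns gapped in both sequences", dropped))
  .as_blocks(blocks, skipped = skipped, dropped = dropped)
}

#' Filter alignment blocks on gap structure
#'
#' Removes blocks whose longest run of columns non-gap in both sequences is
#' shorter than `min_contiguous_nongap` (default 10), and blocks with more
#' gap-containing columns than aligned (non-gap in both) columns.  N counts
#' as a non-gap base for both rules.  Survivor order is preserved; removal
#' counts are stored in attribute `"removed"` and reported with a message.
#'
#' @param blocks an `alignment_blocks` list.
#' @param min_contiguous_nongap minimum length of the longest both-non-gap
#'   run a block must contain.
#' @param require_gaps_le_aligned apply the "more gaps than aligned bases"
#'   removal rule.
#' @return Filtered `alignment_blocks`.  Idempotent.
#' @export
filter_alignment_blocks <- function(blocks, min_contiguous_nongap = 10L,
                                    require_gaps_le_aligned = TRUE) {
  stopifnot(min_contiguous_nongap >= 1L)
  removed_run <- 0L
  removed_gap <- 0L
  keep <- vapply(blocks, function(b) {
    ai <- seq_to_ints(b$ancestor)
    di <- seq_to_ints(b$descendant)
    nongap <- ai != 5L & di != 5L
    runs <- rle(nongap)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (longest < min_contiguous_nongap) {
      removed_run <<- removed_run + 1L
      return(FALSE)
    }
    if (require_gaps_le_aligned && sum(!nongap) > sum(nongap)) {
      removed_gap <<- removed_gap + 1L
      return(FALSE)
    }
    TRUE
  }, NA)
  if (removed_run + removed_gap > 0L)
    message(sprintf(
      "removed %d blocks (< %d contiguous non-gap columns) and %d (more gaps than aligned bases)",
      removed_run, min_contiguous_nongap, removed_gap))
  out <- .as_blocks(unclass(blocks)[keep],
                    skipped = attr(blocks, "skipped"),
                    dropped = attr(blocks, "dropped_columns"))
  attr(out, "removed") <- c(short_run = removed_run, gap_excess = removed_gap)
  out
}

## ---------------------------------------------------------------------------
## Concatenated integer representation used by windowing and counting.
## Blocks are joined with a single separator value (6) so windows can never
## span block boundaries; window validity requires every column to be a
## plain base (A,C,G,T) in both sequences, so N and '-' break runs alike.
## ---------------------------------------------------------------------------

.prep_blocks <- function(blocks) {
  n_b <- length(blocks)
  ai <- vector("list", 2L * n_b)
  di <- vector("list", 2L * n_b)
  sep <- 6L
  for (k in seq_len(n_b)) {
    ai[[2L * k - 1L]] <- seq_to_ints(blocks[[k]]$ancestor)
    di[[2L * k - 1L]] <- seq_to_ints(blocks[[k]]$descendant)
    ai[[2L * k]] <- sep
    di[[2L * k]] <- sep
  }
  anc <- unlist(ai, use.names = FALSE)
  desc <- unlist(di, use.names = FALSE)
  list(anc = anc, desc = desc, n = length(anc),
       good = anc < 4L & desc < 4L)
}

## Valid window start positions for length L, optionally excluding windows
## overlapping (or run-adjacent to) an ancestral CpG dinucleotide.
.window_starts <- function(prep, L, exclude_ancestral_cpg = FALSE) {
  n <- prep$n
  if (n < L) return(integer(0))
  cb <- c(0L, cumsum(!prep$good))
  starts <- seq_len(n - L + 1L)
  valid <- (cb[starts + L] - cb[starts]) == 0L
  if (exclude_ancestral_cpg) {
    ## cpg[j]: ancestral CpG at columns (j, j+1), both inside a gap-free run
    j <- seq_len(n - 1L)
    cpg <- prep$good[j] & prep$good[j + 1L] &
      prep$anc[j] == 1L & prep$anc[j + 1L] == 2L
    cc <- c(0L, cumsum(cpg))
    lo <- pmax(starts - 1L, 1L)
    hi <- pmin(starts + L - 1L, n - 1L)
    valid <- valid & (cc[hi + 1L] - cc[lo]) == 0L
  }
  starts[valid]
}

#' Enumerate alignment windows of length L
#'
#' Emits every set of `L` consecutive alignment columns that are gap-free
#' and N-free in both sequences.  With `exclude_ancestral_cpg`, any window
#' whose ancestral word contains `CG`, or whose first base is a G
#' immediately preceded by an ancestral C in the same gap-free run, or whose
#' last base is a C immediately followed by an ancestral G in the same run,
#' is omitted; this removes every window touching an ancestral CpG so that
#' CpG hypermutability cannot leak into larger-scale statistics.
#'
#' @param block an `alignment_block`.
#' @param L window length (>= 1).
#' @param exclude_ancestral_cpg drop windows overlapping an ancestral CpG.
#' @return `data.frame(start, ancestor, descendant)` with one row per
#'   window, in column order; `start` is the 1-based alignment column.
#' @export
alignment_windows <- function(block, L, exclude_ancestral_cpg = FALSE) {
  stopifnot(L >= 1L)
  prep <- .prep_blocks(list(block))
  starts <- .window_starts(prep, L, exclude_ancestral_cpg)
  if (!length(starts))
    return(data.frame(start = integer(0), ancestor = character(0),
                      descendant = character(0), stringsAsFactors = FALSE))
  data.frame(start = starts,
             ancestor = substring(block$ancestor, starts, starts + L - 1L),
             descendant = substring(block$descendant, starts, starts + L - 1L),
             stringsAsFactors = FALSE)
}

#' Restrict blocks to BED regions
#'
#' Keeps only alignment columns whose ancestral coordinate falls inside a
#' region of the BED file (0-based half-open, as produced by standard
#' genome-arithmetic tools), splitting blocks into sub-blocks at mask
#' boundaries.  Columns where the ancestor is gapped take the coordinate of
#' the most recent ancestral base.  Only `+`-strand blocks with source
#' coordinates are maskable; others are dropped with a warning.
#'
#' @param blocks an `alignment_blocks` list with `source_coords`.
#' @param bed_path path to a BED file.
#' @return `alignment_blocks` of masked sub-blocks (ids suffixed `.1`,
#'   `.2`, ...).
#' @export
apply_bed_mask <- function(blocks, bed_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  out <- list()
  dropped_blocks <- 0L
  for (b in blocks) {
    sc <- b$source_coords
    if (is.null(sc) || !identical(sc$strand, "+")) {
      dropped_blocks <- dropped_blocks + 1L
      next
    }
    ai <- seq_to_ints(b$ancestor)
    ## 1-based ancestral coordinate per column; gap columns inherit the
    ## previous base's coordinate (leading gaps inherit the first base's)
    adv <- as.integer(ai != 5L)
    pos0 <- sc$start + cummax(cumsum(adv)) - 1L
    pos0[pos0 < sc$start] <- sc$start
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(sc$name, IRanges::IRanges(pos0 + 1L, width = 1L)),
      gr)
    keep <- rep(FALSE, b$n_columns)
    keep[S4Vectors::queryHits(hits)] <- TRUE
    if (!any(keep)) next
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    piece <- 0L
    for (r in which(runs$values)) {
      piece <- piece + 1L
      i <- starts[r]; j <- ends[r]
      out[[length(out) + 1L]] <- alignment_block(
        substr(b$ancestor, i, j), substr(b$descendant, i, j),
        block_id = sprintf("%s.%d", b$block_id, piece),
        source_coords = list(name = sc$name, start = pos0[i],
                             end = pos0[j] + 1L, strand = "+"))
    }
  }
  if (dropped_blocks > 0L)
    warning(sprintf("%d blocks without usable +-strand coordinates dropped",
                    dropped_blocks))
  .as_blocks(out)
}

## ---------------------------------------------------------------------------
## Writers (used by the simulators and the CLI)
## ---------------------------------------------------------------------------

#' Write blocks as paired aligned FASTA
#'
#' Records alternate ancestor, descendant; ids share the block id prefix.
#'
#' @param blocks an `alignment_blocks` list.
#' @param path output file.
#' @export
write_paired_fasta <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    writeLines(c(paste0(">", b$block_id, "_ancestor"), b$ancestor,
                 paste0(">", b$block_id, "_descendant"), b$descendant), con)
  }
  invisible(path)
}

#' Write blocks as MAF
#'
#' @param blocks an `alignment_blocks` list.
#' @param path output file.
#' @param ancestor_label,descendant_label species prefixes for the s lines.
#' @export
write_maf <- function(blocks, path, ancestor_label = "ancestor",
                      descendant_label = "descendant") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  offset <- 0
  for (b in blocks) {
    sc <- b$source_coords
    start <- if (!is.null(sc)) sc$start else offset
    srcname <- if (!is.null(sc)) sc$name else b$block_id
    n_anc <- sum(seq_to_ints(b$ancestor) != 5L)
    n_desc <- sum(seq_to_ints(b$descendant) != 5L)
    writeLines(c(
      "", "a score=0",
      sprintf("s %s.%s %d %d + %d %s", ancestor_label, srcname, start,
              n_anc, start + n_anc, b$ancestor),
      sprintf("s %s.%s %d %d + %d %s", descendant_label, srcname, start,
              n_desc, start + n_desc, b$descendant)), con)
    offset <- offset + n_anc
  }
  invisible(path)
}
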