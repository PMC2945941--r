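## ---------------------------------------------------------------------------
## Simulators: ancestors, no-bias controls, context-biased descendants,
## sequencing errors -- plus exact expectation oracles for validation
## ---------------------------------------------------------------------------

#' Construct and validate a single-base substitution model
#'
#' A 4x4 matrix of ancestral-to-descendant probabilities, rows indexed by
#' the ancestral base in order A, C, G, T.  Rows must sum to 1 within 1e-12.
#'
#' @param mat numeric 4x4 matrix.
#' @return The validated matrix with dimnames `ACGT`, class
#'   `single_base_model`.
#' @export
single_base_model <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(identical(dim(mat), c(4L, 4L)), all(mat >= 0))
  if (any(abs(rowSums(mat) - 1) > 1e-12))
    stop("each row of a single-base model must sum to 1")
  dimnames(mat) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  structure(mat, class = c("single_base_model", "matrix", "array"))
}

#' Default human-chimp-like single-base model
#'
#' Transition probability 0.006 and transversion probability 0.0013 per
#' site per branch (about 1% divergence, with each base staying itself
#' 99.14% of the time), matching the single-base divergence levels typical
#' of human/chimpanzee-ancestor alignments: an ancestral C stays C ~99.1%
#' of the time and becomes T (the transition) ~0.6% of the time.
#'
#' @param transition,transversion per-site substitution probabilities.
#' @return A `single_base_model`.
#' @export
default_single_base_model <- function(transition = 0.0060,
                                      transversion = 0.0013) {
  tv <- transversion; ts <- transition
  d <- 1 - ts - 2 * tv
  single_base_model(matrix(c(
    d,  tv, ts, tv,    # A -> A C G T
    tv, d,  tv, ts,    # C (C->T transition)
    ts, tv, d,  tv,    # G (G->A transition)
    tv, ts, tv, d),    # T (T->C transition)
    nrow = 4, byrow = TRUE))
}

#' Generate an i.i.d. random ancestor sequence
#'
#' @param length sequence length (>= 1).
#' @param composition probabilities of A, C, G, T; must sum to 1.
#' @param seed RNG seed; identical seeds give identical sequences.
#' @return A character string over `ACGT`.
#' @export
generate_ancestor <- function(length, composition = rep(0.25, 4), seed = 1L) {
  stopifnot(length >= 1)
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must be 4 non-negative probabilities summing to 1")
  set.seed(seed)
  ints <- sample.int(4L, length, replace = TRUE, prob = composition) - 1L
  intToUtf8(utf8ToInt("ACGT")[ints + 1L])
}

.ints_to_seq <- function(ints) {
  intToUtf8(vapply(c("A", "C", "G", "T", "N", "-"), utf8ToInt, 0L,
                   USE.NAMES = FALSE)[ints + 1L])
}

## descendant draw from an n x 4 row-stochastic probability matrix
.draw_descendant <- function(p, n) {
  u <- stats::runif(n)
  c1 <- p[, 1L]
  c2 <- c1 + p[, 2L]
  c3 <- c2 + p[, 3L]
  (u > c1) + (u > c2) + (u > c3)
}

#' Mutate an ancestor without context effects
#'
#' Each site's descendant base is drawn independently from the ancestral
#' base's row of the single-base model; the alignment is positional (no
#' indels).  Applied to the ancestor of a real dataset with the model
#' estimated from that dataset ([estimate_model()]), this produces the
#' no-bias control: same ancestral counts and single-base divergence, no
#' context effects.
#'
#' @param ancestor character string over `ACGT` (N sites are copied
#'   through unchanged).
#' @param model a `single_base_model`.
#' @param seed RNG seed.
#' @return Descendant sequence of the same length.
#' @export
mutate_no_bias <- function(ancestor, model, seed = 1L) {
  model <- single_base_model(model)
  ai <- seq_to_ints(toupper(ancestor))
  if (any(ai == 5L)) stop("ancestor must be ungapped")
  set.seed(seed)
  base <- ai < 4L
  p <- model[ai[base] + 1L, , drop = FALSE]
  out <- ai
  out[base] <- .draw_descendant(p, sum(base))
  .ints_to_seq(out)
}

#' Estimate a single-base model from observed counts
#'
#' Row `b` of the model is the vector of length-1 pattern proportions
#' `pr(b -> .)` in the count table; this is the model used to build a
#' no-bias control directly from real data.
#'
#' @param table a `pattern_count_table` with length-1 counts for all four
#'   ancestral bases.
#' @return A `single_base_model`.
#' @export
estimate_model <- function(table) {
  tab <- table$tabs[["1"]]
  atab <- table$anc_tabs[["1"]]
  if (is.null(tab) || is.null(atab) || !nrow(atab))
    stop("no length-1 counts in table")
  if (!all(0:3 %in% atab$anc))
    stop("all four ancestral bases must be observed")
  m <- matrix(0, 4, 4)
  for (i in seq_len(nrow(tab))) {
    a <- tab$anc[i] + 1L
    d <- tab$desc[i] + 1L
    m[a, d] <- tab$count[i]
  }
  single_base_model(m / rowSums(m))
}

#' Define a context rule for the biased simulator
#'
#' A rule multiplies the probability of one substitution (`from -> to`)
#' whenever the ancestral context matches `template` with the rule's focal
#' position at the mutating site.  `N` in the template matches any base, so
#' gapped contexts act at a distance: template `"TNG"` with `focal = 1`
#' and `from = "T", to = "C"` raises T->C when a G sits two bases
#' downstream, whatever lies between.
#'
#' @param from,to ancestral and descendant base of the target substitution
#'   (must differ).
#' @param template context word over `A,C,G,T,N`.
#' @param focal 1-based position of the mutating site inside `template`;
#'   the template base there must equal `from`.
#' @param multiplier positive rate multiplier.
#' @return A `context_rule` object.
#' @export
context_rule <- function(from, to, template, focal, multiplier) {
  from <- toupper(from); to <- toupper(to); template <- toupper(template)
  stopifnot(from %in% c("A", "C", "G", "T"), to %in% c("A", "C", "G", "T"),
            from != to, multiplier > 0,
            focal >= 1, focal <= nchar(template))
  ti <- seq_to_ints(template)
  if (any(ti > 4L)) stop("template must be over A,C,G,T,N")
  if (ti[focal] != seq_to_ints(from))
    stop("the template base at the focal position must equal 'from'")
  structure(list(from = from, to = to, template = template,
                 focal = as.integer(focal), multiplier = multiplier),
            class = "context_rule")
}

## n x 4 per-site probability matrix after applying rules to the base model;
## contexts are evaluated on the ancestor only.  Shared by the sampler and
## the exact-expectation oracle.
.site_probs <- function(ai, model, rules) {
  n <- length(ai)
  p <- model[ai + 1L, , drop = FALSE]
  touched <- rep(FALSE, n)
  for (rule in rules) {
    ti <- seq_to_ints(rule$template)
    tl <- length(ti)
    off <- seq_len(tl) - rule$focal
    match_vec <- rep(TRUE, n)
    for (k in seq_len(tl)) {
      if (ti[k] == 4L) next
      shifted <- rep(FALSE, n)
      src <- seq_len(n) + off[k]
      inb <- src >= 1L & src <= n
      shifted[inb] <- ai[src[inb]] == ti[k]
      match_vec <- match_vec & shifted
    }
    hit <- which(match_vec)
    if (!length(hit)) next
    tcol <- seq_to_ints(rule$to) + 1L
    p[hit, tcol] <- p[hit, tcol] * rule$multiplier
    touched[hit] <- TRUE
  }
  if (any(touched)) {
    ht <- which(touched)
    diag_idx <- cbind(ht, ai[ht] + 1L)
    others <- rowSums(p[ht, , drop = FALSE]) - p[diag_idx]
    if (any(others > 1))
      stop("context multipliers drive a diagonal entry below 0; reduce them")
    p[diag_idx] <- 1 - others
  }
  p
}

#' Mutate an ancestor with context-dependent rate multipliers
#'
#' Starts from the single-base model and, at each site, multiplies the
#' off-diagonal entries targeted by every matching rule, then renormalises
#' by adjusting the identity entry.  Sites are drawn independently and
#' contexts are evaluated on the ancestor only (no feedback between sites);
#' sites whose context extends past the sequence ends use only the base
#' model.  With an empty rule set and the same seed the output is identical
#' to [mutate_no_bias()].
#'
#' @inheritParams mutate_no_bias
#' @param rules list of [context_rule()] objects.
#' @return Descendant sequence.
#' @export
mutate_with_context <- function(ancestor, model, rules, seed = 1L) {
  model <- single_base_model(model)
  ai <- seq_to_ints(toupper(ancestor))
  if (any(ai == 5L)) stop("ancestor must be ungapped")
  if (inherits(rules, "context_rule")) rules <- list(rules)
  set.seed(seed)
  base <- which(ai < 4L)
  p <- .site_probs(ai[base], model, .shift_rules_ok(rules))
  out <- ai
  out[base] <- .draw_descendant(p, length(base))
  .ints_to_seq(out)
}

## rules act on the base-only subsequence; with N-free ancestors (the
## simulators never emit N) this is the identity, kept as a seam for
## future masked-ancestor support.
.shift_rules_ok <- function(rules) rules

#' Introduce sequencing errors into alignment blocks
#'
#' Each `A,C,G,T` base is independently replaced, with the per-sequence
#' probability, by one of the three other bases chosen uniformly; gaps and
#' N are untouched.  Error rates of finished and draft genomes are around
#' 0.0001 and 0.0007-0.001 errors per nucleotide respectively.
#'
#' @param blocks an `alignment_blocks` list.
#' @param rate_ancestor,rate_descendant per-base error probabilities.
#' @param seed RNG seed.
#' @return Perturbed `alignment_blocks`.
#' @export
inject_errors <- function(blocks, rate_ancestor, rate_descendant, seed = 1L) {
  stopifnot(rate_ancestor >= 0, rate_ancestor <= 1,
            rate_descendant >= 0, rate_descendant <= 1)
  set.seed(seed)
  perturb <- function(s, rate) {
    if (rate == 0) return(s)
    si <- seq_to_ints(s)
    base <- which(si < 4L)
    hit <- base[stats::runif(length(base)) < rate]
    if (length(hit))
      si[hit] <- (si[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    .ints_to_seq(si)
  }
  out <- lapply(blocks, function(b) {
    alignment_block(perturb(b$ancestor, rate_ancestor),
                    perturb(b$descendant, rate_descendant),
                    block_id = b$block_id, source_coords = b$source_coords)
  })
  .as_blocks(out)
}

#' Wrap an ancestor-descendant pair into alignment blocks
#'
#' Splits a positional (gap-free) alignment into consecutive blocks of the
#' given length so the block bootstrap has realistic resampling units.
#'
#' @param ancestor,descendant equal-length sequences.
#' @param block_length columns per block (the final block keeps the
#'   remainder); default 10 kb.
#' @return An `alignment_blocks` list.
#' @export
as_alignment_blocks <- function(ancestor, descendant, block_length = 10000L) {
  n <- nchar(ancestor)
  stopifnot(nchar(descendant) == n, block_length >= 1L)
  starts <- seq(1L, n, by = block_length)
  ends <- pmin(starts + block_length - 1L, n)
  .as_blocks(lapply(seq_along(starts), function(k) {
    alignment_block(substr(ancestor, starts[k], ends[k]),
                    substr(descendant, starts[k], ends[k]),
                    block_id = sprintf("sim_%d", k))
  }))
}

#' Simulate an ancestor-descendant alignment in one call
#'
#' Generates an i.i.d. ancestor, mutates it (with or without context
#' rules), and wraps the pair into blocks.
#'
#' @param n_columns total alignment columns.
#' @param model a `single_base_model`.
#' @param rules list of [context_rule()]s (empty for a no-bias dataset).
#' @param composition ancestral base composition.
#' @param block_length columns per block.
#' @param seed RNG seed (ancestor and mutation substreams are derived from
#'   it).
#' @return An `alignment_blocks` list.
#' @export
simulate_alignment <- function(n_columns, model = default_single_base_model(),
                               rules = list(), composition = rep(0.25, 4),
                               block_length = 10000L, seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  anc <- generate_ancestor(n_columns, composition, seed = sub[1L])
  desc <- if (length(rules))
    mutate_with_context(anc, model, rules, seed = sub[2L])
  else mutate_no_bias(anc, model, seed = sub[2L])
  as_alignment_blocks(anc, desc, block_length)
}

## ---------------------------------------------------------------------------
## Exact expectation oracles (infinite-data limits of the generator)
## ---------------------------------------------------------------------------

#' Expected conversion proportion under the generator
#'
#' The infinite-data limit of `pr(P)` for a descendant produced by
#' [mutate_with_context()] on an i.i.d. ancestor: all ancestral contexts
#' within the rules' reach are enumerated exactly and weighted by the
#' composition, ignoring sequence-boundary effects (O(1/n)).  This is the
#' brute-force oracle used to validate parameter recovery.
#'
#' @param pattern pattern string.
#' @param model a `single_base_model`.
#' @param rules list of [context_rule()]s.
#' @param composition ancestral base composition.
#' @return Expected proportion.
#' @export
expected_pattern_proportion <- function(pattern,
                                        model = default_single_base_model(),
                                        rules = list(),
                                        composition = rep(0.25, 4)) {
  model <- single_base_model(model)
  if (inherits(rules, "context_rule")) rules <- list(rules)
  pp <- parse_patterns(pattern)
  L <- pp$L
  adig <- digit_at(pp$anc, L, seq_len(L))
  ddig <- digit_at(pp$desc, L, seq_len(L))
  eL <- max(c(0L, vapply(rules, function(r) r$focal - 1L, 0L)))
  eR <- max(c(0L, vapply(rules, function(r) nchar(r$template) - r$focal, 0L)))
  W <- eL + L + eR
  pat_pos <- eL + seq_len(L)
  free <- c(seq_len(eL), pat_pos[adig == 4L], eL + L + seq_len(eR))
  word <- rep(NA_integer_, W)
  word[pat_pos] <- ifelse(adig == 4L, NA_integer_, adig)
  grid <- if (length(free))
    as.matrix(expand.grid(rep(list(0:3), length(free)))) else
    matrix(integer(0), nrow = 1, ncol = 0)
  num <- 0; den <- 0
  for (g in seq_len(nrow(grid))) {
    w <- word
    if (length(free)) w[free] <- grid[g, ]
    weight <- prod(composition[w + 1L])
    p <- .site_probs(w, model, rules)
    conv <- 1
    for (j in which(ddig != 4L))
      conv <- conv * p[pat_pos[j], ddig[j] + 1L]
    num <- num + weight * conv
    den <- den + weight
  }
  num / den
}

#' Expected relative abundance under the generator
#'
#' Applies the recursive relative-abundance definition to the exact
#' expected proportions of [expected_pattern_proportion()], giving the
#' generator's ground-truth rho for any pattern.
#'
#' @inheritParams expected_pattern_proportion
#' @return Expected rho.
#' @export
expected_rho <- function(pattern, model = default_single_base_model(),
                         rules = list(), composition = rep(0.25, 4)) {
  memo <- new.env(parent = emptyenv())
  rec <- function(p) {
    hit <- memo[[p]]
    if (!is.null(hit)) return(hit)
    pr <- expected_pattern_proportion(p, model, rules, composition)
    subs <- subpatterns(p)
    val <- if (!length(subs)) pr else
      pr / prod(vapply(subs, rec, 0))
    assign(p, val, envir = memo)
    val
  }
  rec(pattern)
}
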