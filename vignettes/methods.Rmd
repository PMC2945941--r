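---
title: "Relative abundance of substitution patterns: model, estimators and simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative abundance of substitution patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxbias)
```

## The problem

Nucleotide substitution rates depend on sequence context.  The canonical
example is CpG hypermutability: a methylated C followed by G deaminates to T
at a rate an order of magnitude above the background transition rate, so
`CG->TG` (equivalently `CG->CA` on the other strand) dominates the
dinucleotide substitution spectrum of mammalian genomes.  Most descriptions
of context effects stop at the adjacent base.  This package implements an
empirical framework that measures context effects at pattern sizes of 2-5 bp
and beyond, including *gapped* contexts that act at a distance (e.g. a G two
positions downstream), from nothing more than pairwise ancestor-descendant
alignments.

## Patterns, windows, proportions

A *substitution pattern* `P` of length `L` pairs an ancestral word with a
same-length descendant word, `b1..bL -> b'1..b'L`, where the first and last
ancestral bases are concrete and interior positions may be `N` ("any base",
the same positions in both words).  Patterns with `N` are *gapped* and carry
context at a distance: `TNG->CNG` is "T becomes C when a G sits two bases
downstream, whatever lies between".

Counting slides a window of length `L` over every maximal run of alignment
columns that is gap-free and N-free in both sequences; windows never span
block boundaries.  Each window contributes one observation per gap mask
(there are `2^(L-2)` masks of length `L`).  The *proportion* of a pattern is
the fraction of occurrences of its ancestral word that converted:

    pr(P) = count(anc -> desc) / count(anc)

and its *frequency* `f(P)` is its count divided by the total count of all
same-length patterns, `windows(L) * 2^(L-2)`, so frequencies of one length
sum to 1.  The per-length denominator is a deliberate interpretation: it
makes the frequency weights of the total-bias sum a probability distribution
within each `L`, which is what per-length columns of a total-bias table
require.

## Relative abundance

The relative abundance of a pattern is its observed proportion divided by
the expectation assembled from all of its smaller constituents:

    rho(P) = pr(P)               if L = 1
           = pr(P) / psi(P)      if L > 1

`psi(P)` is the product of `rho` over the subpattern set `S_P`: for every
proper non-empty subset of P's non-N positions, the pattern re-spanned from
the subset's minimum to maximum position with unselected interior positions
masked to N.  For example

    psi(ACT->ATT) = rho(A->A) rho(C->T) rho(T->T)
                    rho(AC->AT) rho(ANT->ANT) rho(CT->TT)

`rho > 1` means the substitution happens more often than its sub-contexts
predict -- a genuine effect at scale `L`, not a repackaged smaller-scale
effect.  This is the property that lets the method *disentangle scales*: a
pure 3-bp process elevates 3-bp rho while leaving every 2-bp rho at 1
(demonstrated by simulation in the acceptance suite).

One subtlety deserves emphasis.  The product over `S_P` runs over *position
subsets*, so a subpattern that arises from several subsets contributes one
factor per subset: `psi(AA->AA) = rho(A->A)^2`.  Collapsing duplicates
would break both the convergence of rho to 1 under a context-free process
and the equivalence of the two algorithms below; both facts are enforced by
tests.

### The fast algorithm

Computing `psi` directly touches all `2^L - 2` subsets.  An equivalent form
needs only the full-length gapped subpatterns `G_P` (interior subsets that
keep both ends):

    rho(P) = pr(P) pr(B2..B_{L-1}) /
             ( pr(B1..B_{L-1}) pr(B2..B_L) gamma(P) ),   L > 2

with `gamma(P)` the product of `rho` over `G_P`.  Interior substrings of a
gapped pattern can carry flanking N; they are trimmed before the `pr`
lookup, and an all-N substring contributes a factor of 1.  Both routes are
implemented (`method = "recursive"` / `"fast"`); the recursive definition is
normative, and the suite verifies agreement to 1e-9 relative over hundreds
of simulated datasets.  Internally both are evaluated levelwise over the
number of non-N positions, vectorised per gap mask, with packed base-5
codes; the fast route's advantage grows with `Lmax` and table density.

### Undefined values

`pr` is undefined when the ancestral word was never seen; `rho` is undefined
when `pr` is undefined, when any subpattern factor is undefined, or when a
zero lands in a denominator.  Undefined values propagate as `NA` with a
reason code (`pr_undefined`, `subpattern_undefined`, `zero_subpattern`,
`zero_denominator`) and are never coerced to 0 or 1; downstream sums skip
them and report how many were skipped, so aggregate numbers remain
auditable.

## Context bias and total context bias

Overrepresentation alone does not measure importance: a pattern with
`rho = 3` that almost never occurs changes genome composition less than a
mildly biased but common one.  The per-pattern impact measure is

    context bias = (rho(P) - 1) * f(P)

(0 exactly for unobserved patterns), and the per-scale aggregate is

    total context bias(L) = sum over length-L patterns of |rho - 1| * f.

The default sum runs over all length-L patterns, gapped and ungapped,
identity and multi-substitution alike; a `single_substitution` filter
reproduces the usual reporting universe of top-pattern tables, and a
`uniform` weighting (`1/N` instead of `f`) separates bias differences from
pattern-composition differences between datasets.  Pattern-level CpG
removal (dropping every pattern whose ancestral word contains `CG`) and
window-level removal (discarding every window that touches an ancestral
CpG, including run-adjacent ones) are both available; they answer slightly
different questions and are kept distinct.

## Significance machinery

**Block bootstrap.**  Alignment columns are locally dependent, so
resampling units are whole blocks: each replicate draws blocks with
replacement until the replicate's column count first reaches the original
total, keeping the overshooting block whole (truncating it would bias
window counts).  The 95% confidence interval is the range of the middle 95%
of replicate values by order statistics -- for 1000 replicates, the 26th to
975th smallest.  Replicate substreams are derived from one master seed, so
runs are bit-reproducible.

**Empirical null p-values.**  A no-bias control regenerates the descendant
from the real ancestor using only the observed single-base divergence
matrix, destroying all context effects while preserving composition and
divergence.  The p-value of a pattern's context bias is the add-one
fraction of null values at least as extreme in absolute value.  Nulls are
pooled per pattern length by default: pooling across same-length patterns
gives p-value resolution far finer than one over the number of control
replicates, which a 0.001 FDR report needs; per-pattern pooling is provided
for comparison.  Benjamini-Hochberg step-up q-values handle multiplicity.

**Comparing datasets.**  Total context bias is sample-size dependent (see
below), so two datasets are compared at a *fixed* column count: each is
block-bootstrapped to the same number of columns many times, and the two
mean total-bias values are compared with
`t = (mean_A - mean_B) / sqrt(var_A + var_B)`, the bootstrap distributions
standing in for the sampling distributions of the two estimates (unequal
variances, no pooling).  The p-value bootstraps the t statistic after
mean-centering both samples.  Scaling by the standard error of the
bootstrap *means* instead would shrink with the number of resamples and
reject everything; the package deliberately does not do that.

### A calibration caveat

`|rho - 1|` is not differentiable at `rho = 1`.  When the truth sits
exactly at the fold -- a completely bias-free process -- the bootstrap is
inconsistent for such functionals and overestimates the sampling variance
(about 1.8x in our measurements), making the comparison test conservative
there (it under-rejects; it never over-rejects).  Real substitution data is
far from the fold (CpG deamination alone gives `rho` near 7.6 for
`CG->TG`), and in that smooth regime the test is well calibrated: the
acceptance suite measures a type-I error of about 5% at `alpha = 0.05`
under same-generator simulations with strong mixed biases, and also asserts
the conservative behaviour at the fold so the caveat stays visible.

### The sample-size artifact

Because `|rho - 1|` folds noise upward, total context bias is positively
biased in small samples: the median no-bias total bias decreases
monotonically with dataset size (verified across 11 doublings from 2 kb to
2 Mb, Spearman rho < -0.9).  Never compare raw total-bias values across
datasets of different sizes; use the fixed-column comparison above.

## The simulators: a stated world

The generators exist to give the estimators a ground truth.

* Ancestors are i.i.d. with a chosen composition (uniform by default).
  Real genomes are not i.i.d.; this isolates the substitution process from
  compositional structure.
* The default single-base model uses a transition probability of 0.006 and
  transversion probabilities of 0.0013 per site, i.e. each base stays
  itself 99.14% of the time -- the divergence regime of human vs the
  human-chimp ancestor, where an ancestral C becomes T about 0.6% of the
  time and each transversion about 0.13%.
* Context rules multiply one off-diagonal entry of the focal site's row
  wherever the ancestral context matches a template (N = any base); the row
  is renormalised through its diagonal.  Contexts are evaluated on the
  ancestor only: no iterative dynamics, no feedback, matching the
  two-state ancestor-descendant framing of the method.  Real data can
  violate this (multiple hits in one window); low-divergence alignments
  keep such windows rare, which is why the method targets closely related
  species.
* No indels are simulated -- the method discards gapped windows anyway.
* Sequencing errors replace each base independently by one of the other
  three; the draft-genome error regime is 1e-4 (finished) to 7e-4 / 1e-3
  (draft) errors per nucleotide.
* Blocks default to 10 kb so the block bootstrap has realistic units.

For any model + rules + composition, `expected_pattern_proportion()`
enumerates all ancestral contexts within the rules' reach exactly and
`expected_rho()` applies the recursive definition to those exact
proportions, giving closed-form ground truth (for a CpG-style rule with
multiplier `m` on a uniform ancestor this reduces to `4m / (m + 3)`).
Parameter-recovery tests require the measured rho to sit within 3 bootstrap
standard errors of this expectation.

A green simulation test therefore establishes that the estimators recover
the generator's truth under i.i.d. ancestors, independent sites and
ancestor-conditioned contexts.  It does not establish anything about
repeat structure, regional rate variation, ancestor misreconstruction or
selection in real genomes.

## Numerical choices

* All proportions are double precision; no rational arithmetic.  The
  worked 6-bp example is asserted to 1e-12, algorithm equivalence to 1e-9
  relative.
* Words are packed as base-5 integers (A=0, C=1, G=2, T=3, N=4), exact in
  doubles to `L = 7`; counting uses `tabulate` over packed codes when the
  bin space is small enough and sparse grouping otherwise.
* Pattern lengths above 7 are rejected; lengths 1-5 are routinely tested.
* Bootstrap CI bounds are order statistics (no interpolation); with
  `n_boot` replicates the bounds are the `floor(0.025 n)+1`-th and
  `n - floor(0.025 n)`-th smallest.
* Ties in empirical p-values are handled by the add-one rule; `p = 1`
  whenever the observed value is 0.

## Known limitations

* Percentile bootstrap intervals on ratio statistics undercover slightly
  at small block counts (measured ~92-96% for a nominal 95%); the
  acceptance band for coverage is 90-99%.
* The comparison test is conservative exactly at the no-bias fold (see
  above).
* Strand pooling is off by default: counting is single-strand, with the
  reverse-complement label reported alongside each pattern.  Pooling
  changes numbers for strand-asymmetric processes.
* BED masking requires ancestor coordinates on the `+` strand.

## A worked example

```{r}
b <- alignment_block("CACGCA", "CATGCA")
tab <- count_patterns(list(b), Lmax = 3)
rho(tab, c("CG->TG", "CNC->TNC", "ACG->ATG"))
total_context_bias(tab, 2)
```

The single `C->T` event inside a CpG makes `CG->TG` three times more common
than its single-base rates predict, and the gapped `CNC->TNC` picks up the
same event at a distance.
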