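---
title: "Minimum-information-loss consensus sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-information-loss consensus sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motto)
```

## The conversion problem

A motif over an alphabet of `n` characters is a `k × n` position weight
matrix (PWM) of per-position probabilities `P(i, j)`, each row summing
to 1. A consensus sequence replaces each row with a character *set*: `[GT]`
says "G or T here", `N` says "anything". The question the package answers
is which set to write at each position so that the consensus distorts the
PWM as little as possible.

The selected set is always a descending-frequency prefix: if a character is
included, every character at least as probable is too. (If a set omitted a
character more probable than one it contains, swapping them can only move
the uniform approximation closer to the column; the test suite verifies
prefix optimality against exhaustive search over all nonempty subsets for
alphabet sizes up to 6, and against 1000 random subsets at size 20.) A
prefix of length `m` is "perceived" as the uniform distribution `C(m)` with
probability `1/m` on each included character — the natural reading of a
consensus string, which records membership but not weights.

The minimal-JSD rule selects

$$m^* = \arg\min_m \; \mathrm{JSD}(C(m), P) + \frac{q}{2}\, m$$

with the Jensen-Shannon divergence (natural logarithm)

$$\mathrm{JSD}(A,B) = \tfrac12 \mathrm{KLD}(A, M) + \tfrac12 \mathrm{KLD}(B, M),
\quad M = \tfrac12 (A+B), \quad
\mathrm{KLD}(A,B) = \sum_j A(j) \ln\frac{A(j)}{B(j)}.$$

KLD here is the standard weighted form; because the mixture `M` is positive
wherever either argument is, no pseudocounts are needed, and terms with
`A(j) = 0` contribute zero. JSD is symmetric and bounded by `ln 2`, which
makes the per-position loss comparable across positions and alphabets and
is the main reason it is preferred over raw KLD (which is infinite when the
perceived distribution excludes a character of positive probability).

The comparator methods share the machinery:

* **mse** substitutes the mean squared error
  `MSE(A,B) = (1/n) Σ (A(j) − B(j))²` for JSD; the same penalty applies.
* **cavener** applies the 1987 rules: the single top character if its
  frequency exceeds 0.50 *and* twice the runner-up; else the top two if
  their sum exceeds 0.75; else N. Both thresholds are applied as strict
  inequalities, so a column at exactly 0.50 falls through to the next rule;
  boundary columns are rare in practice and strictness keeps the rules'
  "exceeds" reading literal. The rules are only defined for 4-letter
  alphabets and error elsewhere.
* **max** takes the single most probable character.

## Tunable parameters

* `penalty` (`q ∈ [0, 1]`, default 0, dimensionless): adds `(q/2)·m` to the
  objective, trading fidelity for definiteness. `q = 0` is the canonical
  minimum-information-loss consensus. At `q = 1` the penalty increment
  (0.5 per extra character) exceeds the largest possible JSD gain (`ln 2 ≈
  0.693` total, and strictly less than 0.5 between consecutive prefix
  lengths), so a single character always wins — exactly the max method.
  The suite asserts this equivalence on 1100 random columns over alphabets
  of size 4 and 20, and that `m*(q)` is non-increasing on a `q`-grid of
  0, 0.1, ..., 1.
* `max_characters` (integer, default unlimited): hard cap on `m`,
  equivalent to truncating the candidate list; it never changes a selection
  the cap does not bind.
* Objective ties break toward smaller `m` (the more definite consensus);
  equal probabilities within a column sort by alphabet order. Both choices
  make output deterministic and penalty monotonicity exact.

## Input and rendering conventions

MEME minimal text format is read and written; the alphabet is inferred from
the character set (ACGT → DNA, ACGU → RNA, the 20 standard amino acids →
protein, anything else custom, case-insensitive). Rows whose raw sum is
within 0.05 of 1 are silently re-normalized — published MEME files
routinely carry 3-decimal rounding — while larger deviations are errors,
since they usually mean a count matrix was supplied. A file without an
ALPHABET line defaults to DNA, following the format's own convention.
Background-frequency lines are parsed into metadata but ignored by
conversion, which uses only `P`.

Rendering styles: `iupac` (one ambiguity code per position, nucleotide
alphabets only), `regex` (bracket classes with characters in descending
frequency order), and `compact` (the default; regex with full-alphabet
classes written as N). For protein or custom alphabets `compact` falls back
to `regex` with a warning rather than an error, because no N convention
exists there and compact is the default style. `--trim` removes
full-alphabet columns at the two ends only — interior Ns carry positional
information (spacing) and are kept; trimming an all-N motif yields an empty
string with a warning. Only exact full-alphabet columns are trimmed; no
ambiguity threshold is applied, keeping the operation involution-free and
predictable.

## The synthetic benchmark

The package re-creates, at desk scale, the evaluation design in which
consensus regex matches are scored against PWM scan hits:

1. `random_motifs()` draws each PWM column from a symmetric Dirichlet
   distribution — the simplest single-knob model of information content
   (concentration 0.05 ≈ near-deterministic columns, 100 ≈ near-uniform).
2. `generate_synthetic_genome()` builds an i.i.d. background sequence and
   plants non-overlapping instances sampled column-wise from each PWM, half
   on the reverse strand, at recorded positions.
3. `scan_pwm()` is the truth oracle: every window on both strands is scored
   by natural-log odds against the background (pseudocount `1e-4`
   substituted for zero PWM cells in the numerator only), and scores are
   converted to p-values through the *exact* distribution of the score
   under the background model, computed by position-wise convolution on a
   discretized score grid (bin width `granularity = 1e-3`). Windows with
   `p < 1e-5` become truth sites scored `−log10 p` (the base of the
   significance log is a display constant; it cannot change
   precision-recall ordering). The suite checks the p-values against
   exhaustive enumeration of all `4^k` k-mers for k ≤ 8: exact agreement on
   the discretized grid, and agreement within one grid bin (`k ×
   granularity` in score) with real-valued enumeration.
4. `scan_consensus()` reports every (overlapping) regex match on both
   strands. A predicted site matching a truth site exactly (interval and
   strand; both scans emit width-`k` windows, so fuzzy matching is
   unnecessary) inherits its significance score; unmatched predictions are
   false positives with score 0 — one defensible reading of how
   consensus-only hits, which have no scan p-value, enter the ranking, and
   it makes the area invariant to duplicated unmatched windows (they add
   no recall, and the zero-score group closes the curve). Truth sites never
   matched are misses; the curve is not extrapolated beyond the attained
   recall.
5. `auprc()` traces precision over recall across descending score
   thresholds and integrates by trapezoid; `compare_methods()` tabulates
   per-motif auPRC per method, excludes motifs with empty truth sets, and
   runs paired-by-motif t-tests on every method pair. Zero-variance
   differences (e.g. two methods producing identical consensus sets for
   every motif) yield a missing p-value with a warning rather than a
   fabricated statistic.

The study conditions used by the acceptance-level comparison are fixed
once: 50 motifs of width 10 at concentration 0.5 (a realistic mix of sharp
and degenerate TF-like columns; width 10 also guarantees the best k-mer can
reach `p < 1e-5` under a uniform background, since `4^{-10} < 10^{-5} <
4^{-8}`), one 1 Mb uniform-background sequence per seed with 20 planted
instances per motif, seeds 11–13. At this scale the expected outcome is
directional — the minimal-JSD method should be at least as good in mean
auPRC as MSE and Cavener, and all three clearly better than max — not a
reproduction of any genome-scale auPRC value, which depends on real TF
collections and a real genome.

What the generator does *not* emulate: genomic base composition and repeat
structure, clustered or overlapping binding sites, database-specific motif
biases, and motif widths varying within a collection. Passing benchmarks
therefore demonstrate correctness of the machinery and the ordering of
methods under clean conditions, not genome-scale effect sizes.

## Numerical choices and degenerate inputs

* `0 · ln(0/x) ≡ 0` throughout; KLD errors if asked for `A(j) > 0` where
  `B(j) = 0` (never reachable through JSD).
* Score-grid granularity `1e-3` keeps discretization error (`≤ k/1000` in
  log-odds units) far below the spacing of distinct k-mer scores for
  realistic widths while the convolution stays a few-hundred-thousand-bin
  vector.
* A motif wider than every scanned sequence yields an empty site table
  with a warning, not an error.
* An empty truth set makes auPRC undefined; `NA` is returned with a
  warning and the motif is excluded from paired tests.
* Coordinates are 0-based half-open internally and in BED output; BED
  scores are `round(1000 · min(1, −log10 p / 10))`.

## Limitations

Columns are treated independently — cross-position dependencies, which
k-mer models capture, are out of scope by construction. The perceived
distribution is always uniform over the included set; weighted consensus
variants would need a different readout convention. Cavener's method is
intentionally reproduced as stated, including its inability to emit
three-character sets. The benchmark's absolute auPRC values are properties
of the synthetic conditions and should not be quoted as genome-scale
performance.
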