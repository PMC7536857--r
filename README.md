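# motto

Convert motif position weight matrices (PWMs) into consensus sequences with
minimum information loss.

A PWM gives `P(i, j)`, the probability of character `j` at motif position
`i`. Consensus strings such as `[GC][AT]GATAAG[GAC]` are the most compact
textual summary of a motif, but the common recipes for producing them are
heuristic: taking the top character per position misrepresents near-uniform
columns, and Cavener's 1987 threshold rules are arbitrary and only defined
for four-letter alphabets. This package selects, at every position, the
descending-frequency character prefix `M* = {S1, ..., Sm*}` whose uniform
"perceived" distribution `C(m)` (probability `1/m` on each included
character) is closest to the observed column:

    m* = argmin_m  JSD(C(m), P) + (q/2) m

where `JSD(A, B) = KLD(A, M)/2 + KLD(B, M)/2` with `M = (A+B)/2`,
`KLD(A, B) = Σ_j A(j) ln(A(j)/B(j))`, and `q ∈ [0, 1]` is an ambiguity
penalty. At `q = 0` (the default) the selection is the canonical
minimum-information-loss consensus; at `q = 1` a single character is always
chosen, which coincides with the maximal-frequency method. Comparator
methods — minimal mean squared error, Cavener's rules, and maximal
frequency — are included, along with MEME-format motif IO over DNA, RNA,
protein, or custom alphabets, three output styles (IUPAC codes, regular
expression, compact), a command line, and a synthetic benchmark that scores
consensus regex occurrences against exact-p-value PWM scan hits by area
under the precision-recall curve (auPRC).

## Worked example

The second position of the human TF P73 motif has frequencies
A 0.077, C 0, G 0.726, T 0.197:

```r
library(motto)
col <- select_m_star(c(A = 0.077, C = 0, G = 0.726, T = 0.197),
                     method_config("motto", penalty = 0), dna_alphabet())
col$m_star
#> [1] 2
col$characters
#> [1] "G" "T"
round(col$per_m_divergence, 4)
#> [1] 0.1059 0.0712 0.0893 0.1729
```

The per-m Jensen-Shannon divergences (m = 1..4) are minimized at m = 2, so
the position is summarized as `[GT]`: writing G alone would discard the
19.7% of binding sites with a T, while N would pretend the column carries
no information. Converting a whole motif and rendering it:

```r
m <- worked_example_motifs()[["GATA2_like"]]
render_consensus(convert_motif(m), m$alphabet, style = "regex")
#> [1] "[GC][AT]GATAAG[GAC]"
```

From the shell (the installed `exec/motto` script; input is a MEME file or
standard input):

```sh
motto -m motto -s compact --trim motifs.meme     # name<TAB>consensus per motif
motto benchmark --motifs motifs.meme --seed 1    # synthetic auPRC comparison
motto synthgen --count 10 --width 10 --seed 1    # random MEME fixtures
```

Flags mirror the library defaults: `-m/--method` (motto, mse, cavener,
max), `-s/--style` (compact, regex, iupac), `-t/--trim`, `-p/--penalty`,
`--maxCharacter`.

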