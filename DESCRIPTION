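Package: motto
Title: Minimum-Information-Loss Consensus Sequences from Position Weight
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts motif position weight matrices (PWMs) into consensus
    sequences with minimal information loss by choosing, at each motif
    position, the descending-frequency character prefix whose uniform
    "perceived" distribution minimizes the Jensen-Shannon divergence to the
    observed column, optionally penalized for ambiguity.  Comparator methods
    (minimal mean squared error, Cavener's 1987 rules, maximal frequency),
    MEME-format motif input/output over DNA, RNA, protein or custom
    alphabets, IUPAC/regex/compact rendering with optional trimming, a
    command-line interface, and a synthetic benchmark that scores consensus
    regex occurrences against exact-p-value PWM scan hits by area under the
    precision-recall curve are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
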