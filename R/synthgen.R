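# Synthetic motif generation: fixtures with controlled information content.

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate random motifs with controlled sharpness
#'
#' Each column is drawn independently from a symmetric Dirichlet
#' distribution: small `concentration` gives sharp, information-rich columns
#' (one dominant character), large `concentration` near-uniform columns.
#' This is the single-knob fixture model used throughout the test suite and
#' the synthetic benchmark.
#'
#' @param count Number of motifs.
#' @param width Positions per motif.
#' @param alphabet An [alphabet()] (default DNA).
#' @param concentration Positive symmetric Dirichlet parameter per column.
#' @param seed Integer seed; the same seed reproduces the same motifs and
#'   the caller's random-number state is left untouched.
#' @param name_prefix Motif names are `<prefix>_1`, `<prefix>_2`, ...
#' @return A list of [motif_record()] objects.
#' @examples
#' random_motifs(2, width = 6, concentration = 0.3, seed = 1)
#' @export
random_motifs <- function(count, width, alphabet = dna_alphabet(),
                          concentration = 0.5, seed = NULL,
                          name_prefix = "motif") {
  stopifnot(count >= 1, width >= 1, concentration > 0)
  n <- length(alphabet$characters)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      g <- matrix(stats::rgamma(width * n, shape = concentration),
        nrow = width
      )
      # guard against all-zero rows from extreme underflow at tiny shapes
      zero <- rowSums(g) == 0
      if (any(zero)) g[zero, ] <- stats::rexp(sum(zero) * n)
      motif_record(sprintf("%s_%d", name_prefix, i), g / rowSums(g), alphabet)
    })
  })
}

#' Worked-example motif fixtures
#'
#' Three small DNA motifs used in examples and tests:
#' \describe{
#'   \item{P73_example}{position 2 carries the P73 column
#'     (A 0.077, C 0, G 0.726, T 0.197) whose minimal-JSD consensus is
#'     \{G, T\}; the flanking positions are constructed near-deterministic
#'     columns, not measured data.}
#'   \item{near_uniform}{a single position (0.26, 0.25, 0.25, 0.24), the
#'     motivating case where maximal frequency misleads and the honest call
#'     is N.}
#'   \item{GATA2_like}{nine constructed columns whose default minimal-JSD
#'     conversion renders as the GATA2 consensus `[GC][AT]GATAAG[GAC]`; the
#'     probabilities are synthetic fixtures chosen to produce that string,
#'     not database entries.}
#' }
#'
#' @return A named list of [motif_record()] objects.
#' @export
worked_example_motifs <- function() {
  alpha <- dna_alphabet()
  sharp <- function(char) {
    p <- rep(0.01, 4)
    p[match(char, alpha$characters)] <- 0.97
    p
  }
  p73 <- rbind(
    sharp("A"),
    c(0.077, 0, 0.726, 0.197),
    sharp("C")
  )
  near_uniform <- matrix(c(0.26, 0.25, 0.25, 0.24), nrow = 1)
  gata2 <- rbind(
    c(0.03, 0.44, 0.50, 0.03), # [GC]
    c(0.50, 0.03, 0.03, 0.44), # [AT]
    sharp("G"),
    sharp("A"),
    sharp("T"),
    sharp("A"),
    sharp("A"),
    sharp("G"),
    c(0.33, 0.30, 0.35, 0.02)  # [GAC]
  )
  list(
    P73_example = motif_record("P73_example", p73, alpha),
    near_uniform = motif_record("near_uniform", near_uniform, alpha),
    GATA2_like = motif_record("GATA2_like", gata2, alpha)
  )
}
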