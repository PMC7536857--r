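# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's selection code paths: divergences
# are recomputed from their definitions and the optimal subset is found by
# exhaustive search over all nonempty subsets, not just prefixes.

oracle_kl <- function(a, b) {
  i <- a > 0
  sum(a[i] * log(a[i] / b[i]))
}

oracle_jsd <- function(a, b) {
  m <- (a + b) / 2
  0.5 * oracle_kl(a, m) + 0.5 * oracle_kl(b, m)
}

oracle_mse <- function(a, b) mean((a - b)^2)

# uniform perceived distribution over an index subset
perceived_vector <- function(subset, n) {
  v <- numeric(n)
  v[subset] <- 1 / length(subset)
  v
}

# exhaustive minimizer of the divergence over ALL nonempty character
# subsets (not only descending-frequency prefixes)
brute_force_best_subset <- function(p, divergence = c("jsd", "mse")) {
  divergence <- match.arg(divergence)
  dfun <- if (divergence == "jsd") oracle_jsd else oracle_mse
  n <- length(p)
  best <- NULL
  best_val <- Inf
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- dfun(perceived_vector(subset, n), p)
    if (val < best_val - 1e-15) {
      best_val <- val
      best <- subset
    }
  }
  list(subset = best, value = best_val)
}

random_column <- function(n, concentration = 1) {
  g <- rgamma(n, shape = concentration)
  while (sum(g) == 0) g <- rgamma(n, shape = concentration)
  g / sum(g)
}

# the printed P73 position-2 frequencies in (A, C, G, T) order
p73_column <- function() c(0.077, 0, 0.726, 0.197)

# a MEME file with the P73-style motif, built in code
p73_meme_text <- function() {
  paste(
    c(
      "MEME version 4",
      "",
      "ALPHABET= ACGT",
      "",
      "strands: + -",
      "",
      "Background letter frequencies",
      "A 0.25 C 0.25 G 0.25 T 0.25",
      "",
      "MOTIF P73",
      "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
      "0.970 0.010 0.010 0.010",
      "0.077 0.000 0.726 0.197",
      "0.010 0.970 0.010 0.010",
      ""
    ),
    collapse = "\n"
  )
}

# all k-mers over ACGT as an integer code matrix (4^k rows, k columns)
all_kmer_codes <- function(k) {
  as.matrix(rev(expand.grid(rev(lapply(seq_len(k), function(i) 1:4)))))
}
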