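# Per-position consensus character-set selection.
#
# A consensus set at a motif position is restricted to descending-frequency
# prefixes: if a character is included, every character at least as frequent
# is too. The "perceived" distribution of an m-character set puts 1/m on
# each included character. The minimal-JSD and minimal-MSE rules choose the
# prefix length m minimizing D(C(m), P) + (q/2) m, where D is the divergence
# and q in [0,1] penalizes ambiguity; q = 1 forces a single character,
# reproducing the maximal-frequency method.

#' Configure a consensus conversion method
#'
#' @param method One of `"motto"` (minimal Jensen-Shannon divergence; alias
#'   `"jsd"`), `"mse"` (minimal mean squared error), `"cavener"` (the 1987
#'   heuristic rules, 4-letter alphabets only) or `"max"` (single maximal
#'   frequency character). Case-insensitive.
#' @param penalty Ambiguity penalty `q` in `[0, 1]`: the objective is
#'   `D(C(m), P) + (q/2) * m`, so larger `q` favors fewer characters; at
#'   `q = 1` a single character is always selected. Applies to `motto` and
#'   `mse`; ignored, with a warning, for `cavener` and `max`.
#' @param max_characters Optional hard upper limit on the number of
#'   characters per position (`motto`/`mse` only).
#' @return An object of class `motto_config`.
#' @examples
#' method_config("motto", penalty = 0.2)
#' @export
method_config <- function(method = c("motto", "jsd", "mse", "cavener", "max"),
                          penalty = 0, max_characters = NULL) {
  method <- match.arg(tolower(method[1L]),
    c("motto", "jsd", "mse", "cavener", "max")
  )
  if (method == "jsd") method <- "motto"
  if (!is.numeric(penalty) || length(penalty) != 1L ||
      is.na(penalty) || penalty < 0 || penalty > 1) {
    stop("`penalty` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.null(max_characters)) {
    max_characters <- as.integer(max_characters)
    if (is.na(max_characters) || max_characters < 1L) {
      stop("`max_characters` must be a positive integer", call. = FALSE)
    }
  }
  if (penalty > 0 && method %in% c("cavener", "max")) {
    warning(sprintf("`penalty` is ignored by the %s method", method),
      call. = FALSE
    )
  }
  structure(
    list(method = method, penalty = penalty, max_characters = max_characters),
    class = "motto_config"
  )
}

config_label <- function(config) {
  if (config$method %in% c("motto", "mse") && config$penalty > 0) {
    sprintf("%s_q%g", config$method, config$penalty)
  } else {
    config$method
  }
}

new_consensus_column <- function(m_star, characters, objective_value,
                                 per_m_divergence, order) {
  structure(
    list(
      m_star = m_star, characters = characters,
      objective_value = objective_value,
      per_m_divergence = per_m_divergence, order = order
    ),
    class = "motto_column"
  )
}

# Descending-probability permutation with ties broken by alphabet order,
# giving deterministic output.
column_order <- function(p) order(-p, seq_along(p))

check_column <- function(p) {
  if (!is.numeric(p) || length(p) < 2L || any(p < 0)) {
    stop("a column must be a nonnegative vector of length >= 2", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("column probabilities must sum to 1", call. = FALSE)
  }
  p / sum(p)
}

#' Select the minimal-divergence consensus set for one column
#'
#' Sorts the column's characters by descending probability, then for each
#' prefix length `m` compares the uniform perceived distribution (1/m on the
#' top `m` characters) with the observed column by Jensen-Shannon divergence
#' (`motto`) or mean squared error (`mse`), plus the ambiguity penalty
#' `(q/2) * m`. The smallest minimizing `m` wins ties, so output is a
#' definite as possible at equal loss.
#'
#' @param p Numeric probability vector, one PWM column (in alphabet order).
#' @param config A [method_config()] with method `motto` or `mse`.
#' @param alphabet The [alphabet()] naming the entries of `p`.
#' @return A `motto_column`: `m_star`, `characters` (the selected characters
#'   in descending probability order), `objective_value` (divergence plus
#'   penalty at the optimum) and `per_m_divergence` (raw divergence for each
#'   candidate `m`).
#' @examples
#' p73 <- c(A = 0.077, C = 0, G = 0.726, T = 0.197)
#' select_m_star(p73, method_config("motto"), dna_alphabet()) # {G, T}
#' @export
select_m_star <- function(p, config, alphabet) {
  if (!config$method %in% c("motto", "mse")) {
    stop("select_m_star applies to the motto and mse methods", call. = FALSE)
  }
  p <- check_column(p)
  n <- length(p)
  if (n != length(alphabet$characters)) {
    stop("column length does not match alphabet size", call. = FALSE)
  }
  ord <- column_order(p)
  sorted <- p[ord]
  mmax <- if (is.null(config$max_characters)) n else min(n, config$max_characters)
  div <- vapply(seq_len(mmax), function(m) {
    perceived <- c(rep(1 / m, m), rep(0, n - m))
    if (config$method == "motto") {
      js_divergence(perceived, sorted)
    } else {
      mean_squared_error(perceived, sorted)
    }
  }, numeric(1L))
  objective <- div + (config$penalty / 2) * seq_len(mmax)
  m_star <- which.min(objective) # first minimum: ties go to smaller m
  new_consensus_column(
    m_star = m_star,
    characters = alphabet$characters[ord[seq_len(m_star)]],
    objective_value = objective[m_star],
    per_m_divergence = div,
    order = ord
  )
}

#' Cavener's 1987 heuristic consensus rules for one column
#'
#' Use the single top character if its frequency strictly exceeds 0.50 and
#' twice the second-highest frequency; else the top two characters if their
#' total strictly exceeds 0.75; else the full 4-character set (N). Boundary
#' values (exactly 0.50 or 0.75) fall through to the next rule. Defined for
#' 4-letter alphabets only: the rules' decision boundaries do not extend to
#' larger character sets.
#'
#' @inheritParams select_m_star
#' @return A `motto_column` with `m_star` in {1, 2, 4}.
#' @export
cavener_column <- function(p, alphabet) {
  p <- check_column(p)
  if (length(p) != 4L || length(alphabet$characters) != 4L) {
    stop("Cavener's rules are defined for 4-letter alphabets only",
      call. = FALSE
    )
  }
  ord <- column_order(p)
  s <- p[ord]
  m <- if (s[1L] > 0.50 && s[1L] > 2 * s[2L]) {
    1L
  } else if (s[1L] + s[2L] > 0.75) {
    2L
  } else {
    4L
  }
  new_consensus_column(
    m_star = m,
    characters = alphabet$characters[ord[seq_len(m)]],
    objective_value = NA_real_,
    per_m_divergence = rep(NA_real_, 4L),
    order = ord
  )
}

#' Maximal-frequency consensus for one column
#'
#' The single most probable character; ties broken by alphabet order.
#'
#' @inheritParams select_m_star
#' @return A `motto_column` with `m_star = 1`.
#' @export
max_column <- function(p, alphabet) {
  p <- check_column(p)
  if (length(p) != length(alphabet$characters)) {
    stop("column length does not match alphabet size", call. = FALSE)
  }
  ord <- column_order(p)
  new_consensus_column(
    m_star = 1L,
    characters = alphabet$characters[ord[1L]],
    objective_value = NA_real_,
    per_m_divergence = rep(NA_real_, length(p)),
    order = ord
  )
}

#' Convert a motif to per-position consensus columns
#'
#' Applies the configured selection rule independently to every position of
#' the motif (the optimal set at a position depends only on that position's
#' probabilities).
#'
#' @param motif A [motif_record()].
#' @param config A [method_config()]; defaults to the minimal-JSD method
#'   with zero ambiguity penalty.
#' @return A list of `motto_column`, one per motif position.
#' @examples
#' m <- worked_example_motifs()[["P73_example"]]
#' cols <- convert_motif(m)
#' cols[[2]]$characters # "G" "T"
#' @export
convert_motif <- function(motif, config = method_config()) {
  if (!inherits(motif, "motto_motif")) {
    stop("`motif` must be a motto_motif", call. = FALSE)
  }
  alpha <- motif$alphabet
  fun <- switch(config$method,
    motto = , mse = function(p) select_m_star(p, config, alpha),
    cavener = function(p) cavener_column(p, alpha),
    max = function(p) max_column(p, alpha)
  )
  lapply(seq_len(nrow(motif$matrix)), function(i) fun(motif$matrix[i, ]))
}
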