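# Rendering consensus columns as text in the three output styles.

full_alphabet_column <- function(column, alphabet) {
  length(column$characters) == length(alphabet$characters)
}

#' Trim full-alphabet columns off both ends
#'
#' Removes leading and trailing columns whose selected set is the whole
#' alphabet (the positions that would render as N); interior full-alphabet
#' columns are kept. A motif that is all-N trims to an empty list (rendered
#' as an empty string, with a warning).
#'
#' @param columns List of `motto_column` from [convert_motif()].
#' @param alphabet The motif's [alphabet()].
#' @return The trimmed list of columns (possibly empty).
#' @export
trim_consensus <- function(columns, alphabet) {
  full <- vapply(columns, full_alphabet_column, logical(1L), alphabet = alphabet)
  keep <- which(!full)
  if (length(keep) == 0L) {
    warning("all positions are full-alphabet; trimming leaves nothing",
      call. = FALSE
    )
    return(list())
  }
  columns[seq(keep[1L], keep[length(keep)])]
}

#' Render consensus columns as a consensus string
#'
#' Three styles:
#' \describe{
#'   \item{iupac}{one ambiguity code per position (e.g. S for \{C,G\});
#'     nucleotide alphabets only.}
#'   \item{regex}{a single character bare, multi-character sets as a regular
#'     expression bracket class with characters in descending frequency
#'     order (e.g. `[GT]`).}
#'   \item{compact}{the default: same as regex except a full-alphabet
#'     position renders as `N` (nucleotide alphabets; other alphabets fall
#'     back to regex with a warning).}
#' }
#'
#' @param columns List of `motto_column` from [convert_motif()].
#' @param alphabet The motif's [alphabet()].
#' @param style `"compact"`, `"regex"` or `"iupac"`.
#' @param trim If `TRUE`, apply [trim_consensus()] first.
#' @return A single consensus string (empty if everything was trimmed).
#' @examples
#' m <- worked_example_motifs()[["GATA2_like"]]
#' render_consensus(convert_motif(m), m$alphabet, style = "regex")
#' @export
render_consensus <- function(columns, alphabet,
                             style = c("compact", "regex", "iupac"),
                             trim = FALSE) {
  style <- match.arg(style)
  if (style == "iupac" && !is_nucleotide(alphabet)) {
    stop("the iupac style requires a 4-letter nucleotide alphabet",
      call. = FALSE
    )
  }
  if (style == "compact" && !is_nucleotide(alphabet)) {
    warning(
      "no N convention for this alphabet; falling back to regex style",
      call. = FALSE
    )
    style <- "regex"
  }
  if (trim) {
    columns <- trim_consensus(columns, alphabet)
  }
  if (length(columns) == 0L) {
    return("")
  }
  tokens <- vapply(columns, function(col) {
    chars <- col$characters
    switch(style,
      iupac = iupac_code(chars, alphabet),
      regex = if (length(chars) == 1L) chars else {
        paste0("[", paste(chars, collapse = ""), "]")
      },
      compact = if (full_alphabet_column(col, alphabet)) "N" else if
      (length(chars) == 1L) chars else {
        paste0("[", paste(chars, collapse = ""), "]")
      }
    )
  }, character(1L))
  paste(tokens, collapse = "")
}

#' Convert motifs and render them in one call
#'
#' Convenience wrapper: [convert_motif()] then [render_consensus()] for each
#' motif.
#'
#' @param motifs A list of [motif_record()] objects (or a single one).
#' @inheritParams convert_motif
#' @inheritParams render_consensus
#' @return A named character vector of consensus strings.
#' @export
motif_consensus <- function(motifs, config = method_config(),
                            style = c("compact", "regex", "iupac"),
                            trim = FALSE) {
  if (inherits(motifs, "motto_motif")) motifs <- list(motifs)
  style <- match.arg(style)
  out <- vapply(motifs, function(m) {
    render_consensus(convert_motif(m, config), m$alphabet,
      style = style, trim = trim
    )
  }, character(1L))
  names(out) <- vapply(motifs, `[[`, character(1L), "name")
  out
}
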