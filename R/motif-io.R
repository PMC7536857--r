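# MEME minimal text format input/output and the motif container.

#' Construct a motif record
#'
#' A named position weight matrix: `k` positions by `n = length(alphabet$characters)`
#' character probabilities, rows summing to 1.
#'
#' @param name Motif identifier.
#' @param matrix Numeric `k x n` matrix of probabilities `P(i, j)`; rows are
#'   re-normalized to sum to 1 exactly. Raw row sums may deviate from 1 by at
#'   most `tolerance` (MEME files routinely carry rounded probabilities);
#'   larger deviation signals a count matrix or corrupt file and is an error.
#' @param alphabet An [alphabet()]; its size must match `ncol(matrix)`.
#' @param metadata Named list of free-form header fields (e.g. MEME
#'   background frequencies); stored, not interpreted.
#' @param tolerance Maximum allowed absolute deviation of a raw row sum
#'   from 1 before re-normalization (default 0.05).
#' @return An object of class `motto_motif`.
#' @examples
#' m <- motif_record("toy", rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)),
#'   dna_alphabet())
#' motif_width(m)
#' @export
motif_record <- function(name, matrix, alphabet, metadata = list(),
                         tolerance = 0.05) {
  if (!inherits(alphabet, "motto_alphabet")) {
    stop("`alphabet` must be a motto_alphabet", call. = FALSE)
  }
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- length(alphabet$characters)
  if (ncol(matrix) != n) {
    stop(sprintf(
      "motif '%s': %d columns but alphabet has %d characters",
      name, ncol(matrix), n
    ), call. = FALSE)
  }
  if (nrow(matrix) < 1L) {
    stop(sprintf("motif '%s': needs at least one position", name),
      call. = FALSE
    )
  }
  if (any(matrix < 0)) {
    bad <- which(rowSums(matrix < 0) > 0)[1L]
    stop(sprintf("motif '%s': negative probability at position %d", name, bad),
      call. = FALSE
    )
  }
  sums <- rowSums(matrix)
  off <- abs(sums - 1) > tolerance
  if (any(off)) {
    stop(sprintf(
      "motif '%s': row %d sums to %.4f (expected 1 within %.2f); not a probability matrix?",
      name, which(off)[1L], sums[which(off)[1L]], tolerance
    ), call. = FALSE)
  }
  matrix <- matrix / sums
  dimnames(matrix) <- list(NULL, alphabet$characters)
  structure(
    list(name = name, alphabet = alphabet, matrix = matrix,
         metadata = metadata),
    class = "motto_motif"
  )
}

#' @rdname motif_record
#' @param motif A `motto_motif`.
#' @export
motif_width <- function(motif) nrow(motif$matrix)

#' @export
print.motto_motif <- function(x, ...) {
  cat(sprintf(
    "<motto_motif> %s: %d positions over %s (%s)\n",
    x$name, motif_width(x), paste(x$alphabet$characters, collapse = ""),
    x$alphabet$kind
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

.read_lines <- function(input) {
  if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\n", input) && (input == "-" || file.exists(input))) {
    if (input == "-") readLines(file("stdin"), warn = FALSE)
    else readLines(input, warn = FALSE)
  } else if (is.character(input)) {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("`input` must be a file path, connection, or character text",
      call. = FALSE
    )
  }
}

#' Parse motifs from MEME minimal text format
#'
#' Reads the MEME minimal motif exchange format: a `MEME version` line, an
#' optional `ALPHABET=` line (default ACGT), optional strand and background
#' frequency lines, then one or more `MOTIF` blocks each with a
#' `letter-probability matrix:` header and one probability row per position.
#'
#' The alphabet kind is inferred from the character set (ACGT is DNA, ACGU is
#' RNA, the 20 standard amino acids protein, anything else custom; input is
#' case-insensitive). Rows are re-normalized to sum to 1; a raw row sum off
#' by more than 0.05 is an error. Background frequency lines are stored in
#' each record's `metadata$background` but play no role in consensus
#' conversion, which uses only the probability matrix.
#'
#' @param input File path (or `"-"` for standard input), connection, or the
#'   file text itself as a character vector.
#' @return A list of [motif_record()] objects in file order.
#' @seealso [write_meme()]
#' @export
parse_meme <- function(input) {
  lines <- .read_lines(input)
  trimmed <- trimws(lines)

  vline <- grep("^MEME version", trimmed)
  if (length(vline) == 0L) {
    stop("not a MEME file: no 'MEME version' line found", call. = FALSE)
  }
  version <- trimmed[vline[1L]]
  if (!grepl("^MEME version\\s+\\S+", version)) {
    stop(sprintf("malformed MEME version line: '%s'", version), call. = FALSE)
  }

  aline <- grep("^ALPHABET", trimmed)
  if (length(aline) > 0L) {
    m <- regmatches(
      trimmed[aline[1L]],
      regexec("^ALPHABET\\s*=\\s*(\\S+)\\s*$", trimmed[aline[1L]])
    )[[1L]]
    if (length(m) != 2L) {
      stop(sprintf("malformed ALPHABET line: '%s'", trimmed[aline[1L]]),
        call. = FALSE
      )
    }
    chars <- strsplit(toupper(m[2L]), "")[[1L]]
  } else {
    chars <- .DNA_CHARS # MEME minimal-format default
  }
  alpha <- alphabet(chars)
  n <- length(chars)

  metadata <- list(version = version)
  sline <- grep("^strands:", trimmed)
  if (length(sline)) metadata$strands <- sub("^strands:\\s*", "", trimmed[sline[1L]])
  bline <- grep("^Background letter frequencies", trimmed)
  if (length(bline)) {
    b <- bline[1L] + 1L
    toks <- strsplit(trimmed[b], "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    nm <- toupper(toks[seq(1, length(toks), by = 2)])
    if (!anyNA(vals) && length(vals) == length(nm)) {
      metadata$background <- stats::setNames(vals, nm)
    }
  }

  mstarts <- grep("^MOTIF\\b", trimmed)
  motifs <- vector("list", length(mstarts))
  bounds <- c(mstarts, length(trimmed) + 1L)
  for (k in seq_along(mstarts)) {
    block <- trimmed[mstarts[k]:(bounds[k + 1L] - 1L)]
    name <- strsplit(block[1L], "\\s+")[[1L]][2L]
    if (is.na(name)) {
      stop(sprintf("MOTIF line without a name (line %d)", mstarts[k]),
        call. = FALSE
      )
    }
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) == 0L) {
      stop(sprintf("motif '%s': no letter-probability matrix header", name),
        call. = FALSE
      )
    }
    hline <- block[hdr[1L]]
    attr_of <- function(key) {
      m <- regmatches(hline, regexec(paste0(key, "\\s*=\\s*(\\S+)"), hline))[[1L]]
      if (length(m) == 2L) m[2L] else NA_character_
    }
    alength <- suppressWarnings(as.integer(attr_of("alength")))
    w <- suppressWarnings(as.integer(attr_of("w")))
    if (!is.na(alength) && alength != n) {
      stop(sprintf(
        "motif '%s': alength= %d does not match alphabet size %d",
        name, alength, n
      ), call. = FALSE)
    }
    rows <- list()
    i <- hdr[1L] + 1L
    while (i <= length(block)) {
      ln <- block[i]
      if (ln == "" || grepl("^URL\\b", ln)) {
        if (length(rows) > 0L) break
        i <- i + 1L
        next
      }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(vals)) break
      if (length(vals) != n) {
        stop(sprintf(
          "motif '%s': position %d has %d values but alphabet has %d characters",
          name, length(rows) + 1L, length(vals), n
        ), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (length(rows) == 0L) {
      stop(sprintf("motif '%s': empty probability matrix", name),
        call. = FALSE
      )
    }
    if (!is.na(w) && w != length(rows)) {
      stop(sprintf(
        "motif '%s': header says w= %d but %d matrix rows found",
        name, w, length(rows)
      ), call. = FALSE)
    }
    motifs[[k]] <- motif_record(
      name, do.call(rbind, rows), alpha,
      metadata = c(metadata, list(matrix_header = hline))
    )
  }
  motifs
}

#' Write motifs in MEME minimal text format
#'
#' The output re-parses with [parse_meme()] to records equal within 1e-6 per
#' matrix cell.
#'
#' @param motifs A list of [motif_record()] objects sharing one alphabet (an
#'   empty list writes a valid header with no MOTIF blocks).
#' @param output File path or connection (default standard output).
#' @return Invisibly, the lines written.
#' @export
write_meme <- function(motifs, output = stdout()) {
  if (inherits(motifs, "motto_motif")) motifs <- list(motifs)
  chars <- NULL
  for (m in motifs) {
    if (!inherits(m, "motto_motif")) {
      stop("`motifs` must be motto_motif objects", call. = FALSE)
    }
    if (is.null(chars)) {
      chars <- m$alphabet$characters
    } else if (!identical(chars, m$alphabet$characters)) {
      stop("all motifs must share one alphabet", call. = FALSE)
    }
  }
  if (is.null(chars)) chars <- .DNA_CHARS
  lines <- c(
    "MEME version 4",
    "",
    paste0("ALPHABET= ", paste(chars, collapse = "")),
    ""
  )
  for (m in motifs) {
    lines <- c(
      lines,
      paste("MOTIF", m$name),
      sprintf(
        "letter-probability matrix: alength= %d w= %d",
        ncol(m$matrix), nrow(m$matrix)
      ),
      apply(m$matrix, 1L, function(r) paste(sprintf("%.8f", r), collapse = " ")),
      ""
    )
  }
  if (inherits(output, "connection")) {
    writeLines(lines, output)
  } else {
    writeLines(lines, con = output)
  }
  invisible(lines)
}
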