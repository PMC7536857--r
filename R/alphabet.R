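# Alphabets over which motifs are defined: an ordered character set plus,
# for nucleotides, a complement map and the IUPAC ambiguity table.

.DNA_CHARS <- c("A", "C", "G", "T")
.RNA_CHARS <- c("A", "C", "G", "U")
.PROTEIN_CHARS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# IUPAC codes keyed by the sorted concatenation of the subset (DNA spelling).
.IUPAC_DNA <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B",
  ACGT = "N"
)

.iupac_table <- function(kind) {
  tab <- .IUPAC_DNA
  if (kind == "rna") names(tab) <- gsub("T", "U", names(tab))
  tab
}

.complement_map <- function(kind) {
  if (kind == "dna") {
    c(A = "T", C = "G", G = "C", T = "A")
  } else {
    c(A = "U", C = "G", G = "C", U = "A")
  }
}

#' Construct a motif alphabet
#'
#' An alphabet is an ordered set of distinct single characters together with
#' a kind tag. Nucleotide alphabets (`dna`, `rna`) additionally carry a
#' complement map and the IUPAC ambiguity table used by the `iupac`
#' rendering style.
#'
#' @param characters Character vector of distinct single characters
#'   (upper-cased internally); length at least 2.
#' @param kind One of `"dna"`, `"rna"`, `"protein"`, `"custom"`. If missing,
#'   inferred from `characters`: the sets ACGT, ACGU and the 20 standard
#'   amino acids map to dna/rna/protein, anything else to custom.
#' @return An object of class `motto_alphabet` with elements `characters`,
#'   `kind`, `complement` (or `NULL`) and `iupac` (or `NULL`).
#' @examples
#' dna_alphabet()
#' alphabet(c("m", "c", "g", "t"))  # custom, e.g. CpG-methylation aware
#' @export
alphabet <- function(characters, kind = NULL) {
  characters <- toupper(as.character(characters))
  if (length(characters) < 2L) {
    stop("an alphabet needs at least 2 characters", call. = FALSE)
  }
  if (anyDuplicated(characters)) {
    stop("alphabet characters must be unique", call. = FALSE)
  }
  if (any(nchar(characters) != 1L)) {
    stop("alphabet characters must be single characters", call. = FALSE)
  }
  if (is.null(kind)) {
    kind <- if (setequal(characters, .DNA_CHARS)) {
      "dna"
    } else if (setequal(characters, .RNA_CHARS)) {
      "rna"
    } else if (setequal(characters, .PROTEIN_CHARS)) {
      "protein"
    } else {
      "custom"
    }
  }
  kind <- match.arg(kind, c("dna", "rna", "protein", "custom"))
  nucleotide <- kind %in% c("dna", "rna")
  structure(
    list(
      characters = characters,
      kind = kind,
      complement = if (nucleotide) .complement_map(kind) else NULL,
      iupac = if (nucleotide) .iupac_table(kind) else NULL
    ),
    class = "motto_alphabet"
  )
}

#' @rdname alphabet
#' @export
dna_alphabet <- function() alphabet(.DNA_CHARS, "dna")

#' @rdname alphabet
#' @export
rna_alphabet <- function() alphabet(.RNA_CHARS, "rna")

#' @rdname alphabet
#' @export
protein_alphabet <- function() alphabet(.PROTEIN_CHARS, "protein")

is_nucleotide <- function(alphabet) alphabet$kind %in% c("dna", "rna")

#' @export
print.motto_alphabet <- function(x, ...) {
  cat(sprintf(
    "<motto_alphabet> %s: %s\n", x$kind,
    paste(x$characters, collapse = "")
  ))
  invisible(x)
}

#' Look up the IUPAC ambiguity code for a character subset
#'
#' @param characters Character vector, a nonempty subset of the alphabet.
#' @param alphabet A nucleotide [alphabet()].
#' @return A single ambiguity code; the order of `characters` is irrelevant.
#' @export
iupac_code <- function(characters, alphabet) {
  if (!is_nucleotide(alphabet)) {
    stop("IUPAC ambiguity codes are defined for nucleotide alphabets only",
      call. = FALSE
    )
  }
  key <- paste(sort(unique(toupper(characters))), collapse = "")
  code <- alphabet$iupac[[key]]
  if (is.null(code)) {
    stop(sprintf("no IUPAC code for character set {%s}", key), call. = FALSE)
  }
  code
}
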