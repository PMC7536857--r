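# Synthetic-scale benchmark: consensus regex occurrence sites versus
# exact-p-value PWM scan hits, summarized per motif by the area under the
# precision-recall curve and compared across methods with a paired t-test.

as_sequences <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(
      as.character(sequences),
      sub("\\s.*$", "", names(sequences))
    )
  }
  if (!is.character(sequences)) {
    stop("`sequences` must be a named character vector or an XStringSet",
      call. = FALSE
    )
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  toupper(sequences)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; record names are
#' truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  as_sequences(Biostrings::readDNAStringSet(path))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

reverse_complement <- function(sequences) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences)))
}

empty_sites <- function() {
  data.frame(
    sequence_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), score = numeric(0), p_value = numeric(0),
    motif = character(0), stringsAsFactors = FALSE
  )
}

#' Plant motif instances in a synthetic background sequence
#'
#' Generates an i.i.d. background sequence of the given length and plants
#' `instances_per_motif` non-overlapping instances of each motif, sampled
#' column-wise from its PWM, at recorded positions; alternate instances go
#' on the reverse strand (their reverse complement is inserted). This is the
#' stand-in genome for benchmarking at desk scale.
#'
#' @param motifs List of DNA [motif_record()] objects.
#' @param length Background sequence length in bases.
#' @param instances_per_motif Instances planted per motif.
#' @param background Length-4 base composition (A, C, G, T); default uniform.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param sequence_id Name of the generated sequence.
#' @return A list with `sequences` (named character vector of length 1) and
#'   `sites` (data frame of planted sites: `sequence_id`, 0-based half-open
#'   `start`/`end`, `strand`, `motif`).
#' @export
generate_synthetic_genome <- function(motifs, length, instances_per_motif,
                                      background = rep(0.25, 4), seed = NULL,
                                      sequence_id = "synth_1") {
  if (inherits(motifs, "motto_motif")) motifs <- list(motifs)
  stopifnot(length >= 1, instances_per_motif >= 0)
  background <- background / sum(background)
  chars <- motifs[[1L]]$alphabet$characters
  if (!identical(chars, .DNA_CHARS)) {
    stop("synthetic genomes are generated over the DNA alphabet",
      call. = FALSE
    )
  }
  widths <- vapply(motifs, motif_width, integer(1L))
  total <- sum(widths) * instances_per_motif
  if (total >= length) {
    stop(sprintf(
      "cannot pack %d planted bases into a length-%d sequence", total, length
    ), call. = FALSE)
  }
  with_seed(seed, {
    seq_chars <- sample(chars, length, replace = TRUE, prob = background)
    occupied <- logical(length)
    recs <- vector("list", length(motifs) * instances_per_motif)
    ri <- 0L
    for (mi in seq_along(motifs)) {
      motif <- motifs[[mi]]
      k <- widths[mi]
      if (k > length) stop("motif wider than the sequence", call. = FALSE)
      for (j in seq_len(instances_per_motif)) {
        placed <- FALSE
        for (attempt in seq_len(10000L)) {
          s <- sample.int(length - k + 1L, 1L)
          if (!any(occupied[s:(s + k - 1L)])) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place a planted site without overlap; sequence too crowded",
            call. = FALSE
          )
        }
        inst <- vapply(seq_len(k), function(i) {
          sample(chars, 1L, prob = motif$matrix[i, ])
        }, character(1L))
        strand <- if (j %% 2L == 0L) "-" else "+"
        if (strand == "-") {
          inst <- strsplit(reverse_complement(paste(inst, collapse = "")), "")[[1L]]
        }
        seq_chars[s:(s + k - 1L)] <- inst
        occupied[s:(s + k - 1L)] <- TRUE
        ri <- ri + 1L
        recs[[ri]] <- data.frame(
          sequence_id = sequence_id, start = s - 1L, end = s - 1L + k,
          strand = strand, motif = motif$name, stringsAsFactors = FALSE
        )
      }
    }
    sites <- if (ri > 0L) do.call(rbind, recs[seq_len(ri)]) else
      empty_sites()[, c("sequence_id", "start", "end", "strand", "motif")]
    list(
      sequences = stats::setNames(paste(seq_chars, collapse = ""), sequence_id),
      sites = sites[order(sites$start), , drop = FALSE]
    )
  })
}

#' Exact discretized null distribution of PWM log-odds scores
#'
#' Computes, by position-wise convolution on a discretized score grid, the
#' exact distribution of the motif's log-odds score (natural log, versus the
#' background composition, with a pseudocount on zero PWM cells) for a
#' random background k-mer. The survival function of this distribution turns
#' window scores into exact p-values, emulating how FIMO assigns
#' significance.
#'
#' @param motif A nucleotide [motif_record()].
#' @param background Base composition for the null model and the log-odds
#'   denominator; default uniform.
#' @param granularity Score-grid bin width (default 1e-3).
#' @param pseudocount Value substituted for zero PWM cells in the log-odds
#'   numerator (default 1e-4); probabilities are not renormalized.
#' @return An object of class `motto_score_dist` with the integerized
#'   per-position score matrix, the pmf and survival function over the
#'   integer grid, and the grid offset.
#' @export
score_distribution <- function(motif, background = NULL, granularity = 1e-3,
                               pseudocount = 1e-4) {
  n <- ncol(motif$matrix)
  if (is.null(background)) background <- rep(1 / n, n)
  stopifnot(length(background) == n, all(background > 0))
  background <- background / sum(background)
  pm <- motif$matrix
  pm[pm == 0] <- pseudocount
  lod <- log(sweep(pm, 2L, background, "/"))
  li <- round(lod / granularity)
  storage.mode(li) <- "integer"
  k <- nrow(li)
  dist <- 1
  lo <- 0L
  for (i in seq_len(k)) {
    vals <- li[i, ]
    nlo <- lo + min(vals)
    nhi <- lo + length(dist) - 1L + max(vals)
    nd <- numeric(nhi - nlo + 1L)
    for (j in seq_len(n)) {
      idx <- seq_along(dist) + (vals[j] + lo - nlo)
      nd[idx] <- nd[idx] + background[j] * dist
    }
    dist <- nd
    lo <- nlo
  }
  sf <- rev(cumsum(rev(dist)))
  structure(
    list(
      scores = li, offset = lo, pmf = dist, sf = sf,
      granularity = granularity, background = background,
      characters = motif$alphabet$characters
    ),
    class = "motto_score_dist"
  )
}

# p-value of integerized total scores under a motto_score_dist
score_pvalue <- function(dist, s) {
  hi <- dist$offset + length(dist$sf) - 1L
  p <- rep(NA_real_, length(s))
  ok <- !is.na(s)
  sv <- pmin(pmax(s[ok], dist$offset), hi)
  p[ok] <- dist$sf[sv - dist$offset + 1L]
  p[ok][s[ok] < dist$offset] <- 1
  p
}

window_scores <- function(li, codes) {
  k <- nrow(li)
  nw <- length(codes) - k + 1L
  if (nw < 1L) {
    return(numeric(0))
  }
  sc <- numeric(nw)
  for (i in seq_len(k)) {
    sc <- sc + li[i, ][codes[i:(i + nw - 1L)]]
  }
  sc
}

#' Scan sequences with a PWM at an exact p-value cutoff
#'
#' Scores every window on both strands by log-odds against the background,
#' converts scores to p-values through the exact discretized score
#' distribution ([score_distribution()]) and reports windows with
#' `p < p_cutoff`, scored as -log10(p). These sites play the role of the
#' FIMO ground truth in the benchmark.
#'
#' @inheritParams score_distribution
#' @param sequences Named character vector of DNA sequences (or an
#'   XStringSet).
#' @param p_cutoff P-value threshold in (0, 1); default 1e-5.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Site data frame: `sequence_id`, 0-based half-open `start`/`end`,
#'   `strand`, `score` (-log10 p), `p_value`, `motif`.
#' @export
scan_pwm <- function(motif, sequences, p_cutoff = 1e-5, background = NULL,
                     granularity = 1e-3, pseudocount = 1e-4,
                     both_strands = TRUE) {
  stopifnot(p_cutoff > 0, p_cutoff < 1)
  sequences <- as_sequences(sequences)
  dist <- score_distribution(motif, background, granularity, pseudocount)
  k <- nrow(dist$scores)
  chars <- dist$characters
  if (all(nchar(sequences) < k)) {
    warning(sprintf("motif '%s' is wider than every sequence", motif$name),
      call. = FALSE
    )
    return(empty_sites())
  }
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (sid in names(sequences)) {
    len <- nchar(sequences[[sid]])
    for (strand in strands) {
      s <- if (strand == "+") sequences[[sid]] else
        reverse_complement(sequences[[sid]])
      codes <- match(strsplit(s, "")[[1L]], chars)
      sc <- window_scores(dist$scores, codes)
      if (length(sc) == 0L) next
      p <- score_pvalue(dist, sc)
      hit <- which(!is.na(p) & p < p_cutoff)
      if (length(hit) == 0L) next
      start0 <- if (strand == "+") hit - 1L else len - hit - k + 1L
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = sid, start = start0, end = start0 + k,
        strand = strand, score = -log10(p[hit]), p_value = p[hit],
        motif = motif$name, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(empty_sites())
  }
  res <- do.call(rbind, out)
  res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
}

consensus_width <- function(pattern) {
  length(regmatches(pattern, gregexpr("\\[[^]]+\\]|.", pattern))[[1L]])
}

#' Find consensus regex occurrences in sequences
#'
#' Reports every (possibly overlapping) match of a fixed-width consensus
#' regular expression — as produced by [render_consensus()] with the
#' `regex` style — on both strands; the reverse strand is searched through
#' the reverse-complemented sequence with coordinates mapped back. Matches
#' carry score 0 until [auprc()] assigns them the significance of the truth
#' sites they recover.
#'
#' @param pattern Consensus regular expression (plain characters and bracket
#'   classes only, one token per motif position).
#' @param sequences Named character vector of DNA sequences (or an
#'   XStringSet).
#' @param both_strands Search the reverse strand too (default `TRUE`).
#' @return Site data frame as in [scan_pwm()], with `score = 0` and
#'   `p_value = NA`.
#' @export
scan_consensus <- function(pattern, sequences, both_strands = TRUE) {
  sequences <- as_sequences(sequences)
  k <- consensus_width(pattern)
  if (k == 0L) stop("empty consensus pattern", call. = FALSE)
  look <- paste0("(?=", pattern, ")")
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (sid in names(sequences)) {
    len <- nchar(sequences[[sid]])
    for (strand in strands) {
      s <- if (strand == "+") sequences[[sid]] else
        reverse_complement(sequences[[sid]])
      m <- gregexpr(look, s, perl = TRUE)[[1L]]
      pos <- as.integer(m)
      pos <- pos[pos > 0L & pos + k - 1L <= len]
      if (length(pos) == 0L) next
      start0 <- if (strand == "+") pos - 1L else len - pos - k + 1L
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = sid, start = start0, end = start0 + k,
        strand = strand, score = 0, p_value = NA_real_,
        motif = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(empty_sites())
  }
  res <- do.call(rbind, out)
  res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
}

site_key <- function(sites) {
  paste(sites$sequence_id, sites$start, sites$strand, sep = "\r")
}

#' Area under the precision-recall curve for consensus sites against truth
#'
#' Truth sites (PWM scan hits with -log10 p scores) are the positives. A
#' predicted consensus site matching a truth site exactly (same sequence,
#' interval and strand) inherits that site's significance score; predicted
#' sites absent from the truth are false positives with score 0; truth
#' sites never predicted are misses. The precision-recall curve is traced
#' over descending score thresholds and integrated by the trapezoidal rule
#' over recall (no extrapolation beyond the attained recall).
#'
#' @param predicted Site data frame from [scan_consensus()].
#' @param truth Site data frame from [scan_pwm()].
#' @return auPRC in `[0, 1]`, or `NA` with a warning if `truth` is empty.
#' @export
auprc <- function(predicted, truth) {
  if (nrow(truth) == 0L) {
    warning("empty truth set: auPRC undefined", call. = FALSE)
    return(NA_real_)
  }
  if (nrow(predicted) == 0L) {
    return(0)
  }
  hit <- match(site_key(predicted), site_key(truth))
  score <- ifelse(is.na(hit), 0, truth$score[hit])
  matched <- !is.na(hit)
  o <- order(-score)
  score <- score[o]
  matched <- matched[o]
  last <- which(!duplicated(score, fromLast = TRUE))
  tp <- cumsum(matched)[last]
  fp <- cumsum(!matched)[last]
  recall <- tp / nrow(truth)
  precision <- tp / (tp + fp)
  r <- c(0, recall)
  p <- c(precision[1L], precision)
  sum(diff(r) * (p[-length(p)] + p[-1L]) / 2)
}

#' Benchmark consensus methods against PWM scan truth
#'
#' For each motif, the truth set is the exact-p-value PWM scan
#' ([scan_pwm()]) of the sequences; each configured method converts the
#' motif to a consensus regex ([render_consensus()], regex style, no
#' trimming so widths stay aligned), its occurrences are matched against
#' the truth, and the area under the precision-recall curve is recorded.
#' Mean and standard error per method and paired (by motif) t-tests for
#' every method pair summarize the comparison. Motifs whose truth set is
#' empty are excluded from pairing and listed in the report.
#'
#' @param motifs List of DNA [motif_record()] objects (at least 2 usable).
#' @param sequences Named character vector of DNA sequences (or XStringSet).
#' @param configs List of [method_config()] objects; default the four
#'   methods at their defaults.
#' @inheritParams scan_pwm
#' @return An object of class `motto_benchmark`: `auprc` (motif x method
#'   matrix), `mean`, `se`, `t_pvalues` (paired t-test p-value matrix, `NA`
#'   with a warning on zero-variance differences), `excluded` (motif names
#'   with empty truth), `degenerate` (motif/method pairs whose consensus
#'   matches every window).
#' @export
compare_methods <- function(motifs, sequences,
                            configs = list(
                              method_config("motto"),
                              method_config("mse"),
                              method_config("cavener"),
                              method_config("max")
                            ),
                            p_cutoff = 1e-5, background = NULL,
                            granularity = 1e-3, pseudocount = 1e-4) {
  if (inherits(motifs, "motto_motif")) motifs <- list(motifs)
  sequences <- as_sequences(sequences)
  labels <- names(configs)
  if (is.null(labels)) {
    labels <- vapply(configs, config_label, character(1L))
  }
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  mnames <- vapply(motifs, `[[`, character(1L), "name")
  au <- matrix(NA_real_,
    nrow = length(motifs), ncol = length(configs),
    dimnames = list(mnames, labels)
  )
  excluded <- character(0)
  degenerate <- list()
  for (i in seq_along(motifs)) {
    motif <- motifs[[i]]
    truth <- scan_pwm(motif, sequences,
      p_cutoff = p_cutoff, background = background,
      granularity = granularity, pseudocount = pseudocount
    )
    if (nrow(truth) == 0L) {
      excluded <- c(excluded, motif$name)
      next
    }
    for (j in seq_along(configs)) {
      cols <- convert_motif(motif, configs[[j]])
      pattern <- render_consensus(cols, motif$alphabet, style = "regex")
      if (all(vapply(cols, full_alphabet_column, logical(1L),
        alphabet = motif$alphabet
      ))) {
        degenerate[[length(degenerate) + 1L]] <- data.frame(
          motif = motif$name, method = labels[j], stringsAsFactors = FALSE
        )
      }
      pred <- scan_consensus(pattern, sequences)
      au[i, j] <- auprc(pred, truth)
    }
  }
  usable <- !(mnames %in% excluded)
  if (sum(usable) < 2L) {
    stop("fewer than 2 motifs with non-empty truth sets", call. = FALSE)
  }
  aum <- au[usable, , drop = FALSE]
  tmat <- matrix(NA_real_,
    ncol(aum), ncol(aum),
    dimnames = list(labels, labels)
  )
  for (a in seq_len(ncol(aum))) {
    for (b in seq_len(ncol(aum))) {
      if (a >= b) next
      d <- aum[, a] - aum[, b]
      if (stats::sd(d) == 0) {
        warning(sprintf(
          "zero-variance paired differences between %s and %s; t-test p-value is NA",
          labels[a], labels[b]
        ), call. = FALSE)
      } else {
        tmat[a, b] <- tmat[b, a] <-
          stats::t.test(aum[, a], aum[, b], paired = TRUE)$p.value
      }
    }
  }
  structure(
    list(
      auprc = aum,
      mean = colMeans(aum),
      se = apply(aum, 2L, stats::sd) / sqrt(nrow(aum)),
      t_pvalues = tmat,
      excluded = excluded,
      degenerate = if (length(degenerate)) do.call(rbind, degenerate) else
        data.frame(motif = character(0), method = character(0))
    ),
    class = "motto_benchmark"
  )
}

#' @export
print.motto_benchmark <- function(x, ...) {
  cat(sprintf(
    "<motto_benchmark> %d motifs x %d methods\n",
    nrow(x$auprc), ncol(x$auprc)
  ))
  cat("mean auPRC (± s.e.):\n")
  for (m in colnames(x$auprc)) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$mean[[m]], x$se[[m]]))
  }
  if (length(x$excluded)) {
    cat("excluded (empty truth):", paste(x$excluded, collapse = ", "), "\n")
  }
  if (nrow(x$degenerate)) {
    cat(sprintf("%d degenerate all-N consensus conversions\n", nrow(x$degenerate)))
  }
  invisible(x)
}

#' Write occurrence sites as BED6
#'
#' Columns: sequence, 0-based half-open start/end, motif name, score
#' `round(1000 * min(1, -log10(p) / 10))`, strand.
#'
#' @param sites Site data frame from [scan_pwm()] or [scan_consensus()].
#' @param output File path or connection.
#' @return Invisibly, `sites`.
#' @export
sites_to_bed <- function(sites, output = stdout()) {
  bed <- data.frame(
    chrom = sites$sequence_id,
    start = sites$start,
    end = sites$end,
    name = ifelse(is.na(sites$motif), ".", sites$motif),
    score = round(1000 * pmin(1, sites$score / 10)),
    strand = sites$strand
  )
  utils::write.table(bed, output,
    quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  invisible(sites)
}
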