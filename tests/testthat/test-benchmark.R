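# helper: real-score exhaustive enumeration oracle for the scanner
enumerate_pvalue <- function(motif, threshold, background = rep(0.25, 4),
                             pseudocount = 1e-4) {
  pm <- motif$matrix
  pm[pm == 0] <- pseudocount
  lod <- log(sweep(pm, 2, background, "/"))
  codes <- all_kmer_codes(nrow(pm))
  scores <- vapply(seq_len(nrow(codes)), function(r) {
    sum(lod[cbind(seq_len(ncol(codes)), codes[r, ])])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(codes)), function(r) {
    prod(background[codes[r, ]])
  }, numeric(1))
  sum(probs[scores >= threshold])
}

test_that("synthetic genomes are deterministic and plant what they claim", {
  motifs <- random_motifs(2, width = 10, concentration = 0.1, seed = 6)
  a <- generate_synthetic_genome(motifs, 5000, 5, seed = 13)
  b <- generate_synthetic_genome(motifs, 5000, 5, seed = 13)
  expect_identical(a, b)
  expect_equal(nchar(a$sequences), c(synth_1 = 5000L))
  expect_equal(nrow(a$sites), 10L)
  expect_true(all(a$sites$end - a$sites$start == 10L))
  expect_setequal(unique(a$sites$strand), c("-", "+"))
  # planted intervals do not overlap
  s <- a$sites[order(a$sites$start), ]
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  # FASTA round trip preserves bytes
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$sequences, fa)
  expect_identical(read_fasta(fa), a$sequences)
  expect_error(
    generate_synthetic_genome(motifs, 50, 5, seed = 1),
    "pack"
  )
})

test_that("a pure background scan is calibrated to length x p-cutoff", {
  motif <- random_motifs(1, width = 10, concentration = 0.3, seed = 14)[[1L]]
  g <- generate_synthetic_genome(list(motif), 2e5, 0, seed = 15)
  expect_equal(nrow(g$sites), 0L)
  cutoff <- 1e-3
  hits <- scan_pwm(motif, g$sequences, p_cutoff = cutoff)
  expected <- 2 * (2e5 - 10 + 1) * cutoff # both strands
  expect_gt(nrow(hits), expected * 0.5)
  expect_lt(nrow(hits), expected * 1.5)
})

test_that("planted instances of a sharp motif are recovered at p < 1e-5", {
  motif <- random_motifs(1, width = 10, concentration = 0.05, seed = 9)[[1L]]
  g <- generate_synthetic_genome(list(motif), 5e4, 100, seed = 3)
  truth <- scan_pwm(motif, g$sequences)
  planted <- paste(g$sites$sequence_id, g$sites$start, g$sites$strand)
  found <- paste(truth$sequence_id, truth$start, truth$strand)
  expect_gte(sum(planted %in% found), 95L)
})

test_that("scanner p-values agree with exhaustive k-mer enumeration", {
  set.seed(51)
  g <- 1e-3
  for (k in c(4, 6, 8)) {
    motif <- random_motifs(1, width = k, concentration = 0.4,
      seed = 50 + k
    )[[1L]]
    dist <- score_distribution(motif, granularity = g)
    # integerized enumeration must reproduce the DP survival function exactly
    codes <- all_kmer_codes(k)
    iscores <- vapply(seq_len(nrow(codes)), function(r) {
      sum(dist$scores[cbind(seq_len(k), codes[r, ])])
    }, numeric(1))
    chars <- apply(codes, 1, function(cd) {
      paste(c("A", "C", "G", "T")[cd], collapse = "")
    })
    pm <- motif$matrix
    pm[pm == 0] <- 1e-4
    lod <- log(pm / 0.25)
    probe <- sample(nrow(codes), 25)
    for (r in probe) {
      hit <- scan_pwm(motif, c(w = chars[r]),
        p_cutoff = 1 - 1e-12, both_strands = FALSE, granularity = g
      )
      expect_equal(nrow(hit), 1L)
      p_dp <- hit$p_value
      p_int <- mean(iscores >= iscores[r]) # uniform background
      expect_equal(p_dp, p_int, tolerance = 1e-12)
      # and stay within one discretization bin of the real-score enumeration
      s_real <- sum(lod[cbind(seq_len(k), codes[r, ])])
      expect_lte(p_dp, enumerate_pvalue(motif, s_real - k * g))
      expect_gte(p_dp, enumerate_pvalue(motif, s_real + k * g))
    }
  }
})

test_that("the best k-mer's p-value is the survival mass at the top score", {
  motif <- random_motifs(1, width = 5, concentration = 0.2, seed = 16)[[1L]]
  best <- paste(c("A", "C", "G", "T")[apply(motif$matrix, 1, which.max)],
    collapse = ""
  )
  hit <- scan_pwm(motif, c(x = best),
    p_cutoff = 1 - 1e-12,
    both_strands = FALSE
  )
  expect_equal(nrow(hit), 1L)
  # no k-mer scores above the best one, so the p-value is exactly the
  # survival mass at the top attained score bin: at least the background
  # probability of the single best k-mer, and reproduced by enumeration
  dist <- score_distribution(motif)
  codes <- all_kmer_codes(5)
  iscores <- vapply(seq_len(nrow(codes)), function(r) {
    sum(dist$scores[cbind(1:5, codes[r, ])])
  }, numeric(1))
  expect_equal(hit$p_value, mean(iscores >= max(iscores)), tolerance = 1e-12)
  expect_gte(hit$p_value, 0.25^5)
  expect_equal(hit$score, -log10(hit$p_value))
})

test_that("reverse-complement hits are reported on the minus strand", {
  motif <- random_motifs(1, width = 8, concentration = 0.05, seed = 18)[[1L]]
  best <- paste(c("A", "C", "G", "T")[apply(motif$matrix, 1, which.max)],
    collapse = ""
  )
  pad <- strrep("A", 20)
  fwd <- paste0(pad, best, pad)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd))
  )
  h_fwd <- scan_pwm(motif, c(s = fwd), p_cutoff = 0.5)
  h_rc <- scan_pwm(motif, c(s = rc), p_cutoff = 0.5)
  top_fwd <- h_fwd[which.max(h_fwd$score), ]
  top_rc <- h_rc[which.max(h_rc$score), ]
  expect_equal(top_fwd$start, 20L)
  expect_equal(top_fwd$strand, "+")
  expect_equal(top_rc$start, 20L)
  expect_equal(top_rc$strand, "-")
  expect_equal(top_rc$score, top_fwd$score)
})

test_that("consensus regex scanning finds overlapping matches on both strands", {
  hits <- scan_consensus("GATAAG", c(s = "TTGATAAGTT"))
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  expect_equal(hits$start[hits$strand == "+"], 2L)
  expect_equal(hits$end[hits$strand == "+"], 8L)
  # the reverse strand sees CTTATC
  rc_hits <- scan_consensus("GATAAG", c(s = "TTCTTATCTT"))
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 2L)
  # overlaps are all reported: AA in AAAA at offsets 0,1,2
  ov <- scan_consensus("AA", c(s = "AAAA"))
  expect_equal(sort(ov$start[ov$strand == "+"]), 0:2)
  # a [GT] class matches both letters
  cls <- scan_consensus("[GT]", c(s = "GCT"), both_strands = FALSE)
  expect_equal(sort(cls$start), c(0L, 2L))
})

test_that("auPRC follows the matching and scoring conventions", {
  mk <- function(starts, strand = "+", score = 0, p = NA_real_) {
    data.frame(
      sequence_id = "s", start = starts, end = starts + 10,
      strand = strand, score = score, p_value = p, motif = "m",
      stringsAsFactors = FALSE
    )
  }
  truth <- mk(seq(0, 90, by = 10), score = 10:1)
  expect_equal(auprc(truth, truth), 1)
  expect_equal(auprc(mk(1000 + seq(0, 40, 10)), truth), 0)
  expect_warning(expect_true(is.na(auprc(mk(0), mk(0)[0, ]))),
    "empty truth"
  )
  expect_equal(auprc(mk(0)[0, ], truth), 0)
  # hand-enumerated example: truth has 10 sites; 5 predictions match sites
  # scored 5,4,3,2,1 and 3 predictions are unmatched (score 0).
  # PR points walk recall 0.1..0.5 at precision 1, then the score-0 group
  # adds no recall, so the trapezoidal area is 0.5.
  truth10 <- mk(seq(0, 90, by = 10), score = c(5, 4, 3, 2, 1, 9, 9, 9, 9, 9))
  pred <- mk(c(seq(0, 40, by = 10), 500, 510, 520))
  expect_equal(auprc(pred, truth10), 0.5)
  # invariant to record order and to duplicated unmatched windows
  expect_equal(auprc(pred[sample(nrow(pred)), ], truth10), 0.5)
  more_fp <- rbind(pred, mk(c(600, 610, 620, 630)))
  expect_equal(auprc(more_fp, truth10), 0.5)
  # strand must match exactly
  flipped <- truth
  flipped$strand <- "-"
  expect_equal(auprc(flipped, truth), 0)
})

test_that("compare_methods pairs by motif and handles degenerate input", {
  motifs <- random_motifs(3, width = 10, concentration = 0.15, seed = 22)
  g <- generate_synthetic_genome(motifs, 3e4, 10, seed = 22)
  # two identical configs: differences are all zero
  expect_warning(
    rep2 <- compare_methods(motifs, g$sequences,
      configs = list(a = method_config("motto"), b = method_config("motto"))
    ),
    "zero-variance"
  )
  expect_equal(unname(rep2$auprc[, "a"]), unname(rep2$auprc[, "b"]))
  expect_true(is.na(rep2$t_pvalues["a", "b"]))
  expect_error(
    compare_methods(motifs[1], g$sequences,
      configs = list(method_config("motto"))
    ),
    "2 motifs"
  )
})

test_that("penalty-1 consensus sites are a subset of max-method sites", {
  motifs <- random_motifs(10, width = 6, concentration = 0.8, seed = 26)
  for (m in motifs) {
    rx_pen <- render_consensus(
      convert_motif(m, method_config("motto", penalty = 1)),
      m$alphabet,
      style = "regex"
    )
    rx_max <- render_consensus(
      convert_motif(m, method_config("max")),
      m$alphabet,
      style = "regex"
    )
    expect_identical(rx_pen, rx_max)
  }
})
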