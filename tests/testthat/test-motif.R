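test_that("IUPAC degeneracy and strand symmetry behave as defined", {
  g <- Biostrings::DNAStringSet(c(c1 = "TTGTAAACATTGTAAATATTGTAAAGATT"))
  hits <- scan_iupac(g, "GTAAAYA")
  plus <- hits[hits$strand == "+", ]
  # GTAAACA and GTAAATA match, GTAAAGA does not
  expect_equal(plus$start, c(3L, 12L))
  # a sequence holding only the reverse complement: one minus-strand hit
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0("TT", revcomp_str("GTAAACA"), "TT")))
  h2 <- scan_iupac(g2, "GTAAAYA")
  expect_equal(nrow(h2[h2$strand == "+", ]), 0L)
  expect_equal(nrow(h2[h2$strand == "-", ]), 1L)
  expect_equal(h2$five_prime[h2$strand == "-"], h2$end[h2$strand == "-"])
  expect_error(scan_iupac(g, "GTAAAZA"), "IUPAC")
})

test_that("scanner matches the naive position-by-position oracle exactly", {
  set.seed(501)
  s <- rdna(10000)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  for (motif in c("GTAAAYA", "ACGCTC", "RNYT")) {
    hits <- scan_iupac(g, motif)
    expect_equal(sort(hits$start[hits$strand == "+"]),
                 naive_iupac_hits(s, motif, "+"))
    expect_equal(sort(hits$start[hits$strand == "-"]),
                 naive_iupac_hits(s, motif, "-"))
  }
  # hit density on random sequence is near the per-position match probability
  hits <- scan_iupac(g, "GTAAAYA")
  p_match <- 2 / 4^7
  expected <- 2 * (10000 - 6) * p_match
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 3)
})

test_that("both-strand scanning equals scanning sequence plus reverse complement", {
  set.seed(502)
  s <- rdna(3000)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  both <- scan_iupac(g, "GTAAAYA", both_strands = TRUE)
  fwd_only <- scan_iupac(g, "GTAAAYA", both_strands = FALSE)
  grc <- Biostrings::DNAStringSet(c(c1 = revcomp_str(s)))
  rc_fwd <- scan_iupac(grc, "GTAAAYA", both_strands = FALSE)
  expect_equal(nrow(both), nrow(fwd_only) + nrow(rc_fwd))
  # minus-strand five-prime positions map onto the reverse-complement scan
  minus <- both[both$strand == "-", ]
  expect_setequal(3000 + 1 - minus$five_prime, rc_fwd$start)
})

test_that("antisense origins near motifs are flagged within the window", {
  hits <- data.frame(motif = "GTAAAYA", chrom = "chrI", strand = "+",
                     start = 1000L, end = 1006L, five_prime = 1000L)
  calls <- data.frame(gene_id = c("a", "b"), chrom = "chrI",
                      origin_pos = c(1100L, 1700L))
  res <- antisense_near_motif(calls, hits, window = 500L)
  expect_equal(res$flags, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  res0 <- antisense_near_motif(calls, hits[0, ], window = 500L)
  expect_equal(res0$fraction, 0)
  # distances are 100 and 700 nt: windows 200 / 500 / 1000
  expect_equal(res$sensitivity$fraction, c(0.5, 0.5, 1))
})

test_that("planted motif fractions are recovered from generated genomes", {
  fractions <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, motif_fraction = 0.8,
                      arch = list(new_antisense = 10L, mid_meiotic_discrete = 2L,
                                  mid_meiotic_utr3 = 2L, fkh2_responsive = 2L,
                                  internal_bidirectional = 1L, fold_change = 1L,
                                  spliced = 1L, unspliced = 1L),
                      n_genes = 22L)
    gen <- generate_genome_and_annotation(cfg)
    hits <- scan_iupac(gen$genome, "GTAAAYA")
    origins <- astiler:::truth_antisense_origins(gen, "new_antisense")
    antisense_near_motif(origins, hits, window = 200L)$fraction
  }, numeric(1))
  expect_equal(mean(fractions), 0.8, tolerance = 0.05 / 0.8)
})

test_that("common k-mer discovery finds planted words with sane p-values", {
  set.seed(503)
  seqs <- vapply(1:3, function(i) {
    s <- rdna(400)
    paste0(substr(s, 1, 180), "ACGCTC", substr(s, 187, 400))
  }, character(1))
  res <- find_common_kmer(seqs, 6)
  expect_true("ACGCTC" %in% res$kmer)
  expect_equal(res$n_sequences_containing[res$kmer == "ACGCTC"], 3L)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # single sequence "AAAA": the word is present with p = q (m = 1)
  r1 <- find_common_kmer("AAAA", 4)
  expect_equal(r1$kmer, "AAAA")
  expect_equal(r1$p_value, kmer_contain_prob("AAAA", 4))
  expect_equal(r1$p_value, 4^-4, tolerance = 1e-12)
  expect_error(find_common_kmer(c("ACGT", "AC"), 3), "shortest")
})

test_that("containment significance grows with the number of carriers", {
  set.seed(504)
  seqs <- vapply(1:4, function(i) rdna(200), character(1))
  seqs[1:3] <- paste0("TTTACGCTCGG", substr(seqs[1:3], 12, 200))
  res <- find_common_kmer(seqs, 6, min_sequences = 1L)
  # at fixed margins, a word in more sequences is never less significant
  agg <- tapply(res$p_value, res$n_sequences_containing, stats::median)
  counts <- as.integer(names(agg))
  expect_true(all(diff(agg[order(counts)]) <= 0))
  # window-independence variant stays available and close at k = 6
  rw <- find_common_kmer(seqs, 6, min_sequences = 3L, p_method = "windows")
  re <- find_common_kmer(seqs, 6, min_sequences = 3L)
  shared <- intersect(rw$kmer, re$kmer)
  expect_equal(rw$p_value[match(shared, rw$kmer)],
               re$p_value[match(shared, re$kmer)], tolerance = 0.1)
})
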