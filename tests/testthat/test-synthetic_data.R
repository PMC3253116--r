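test_that("generator is deterministic and honors degenerate configs", {
  cfg <- sim_config(seed = 7, n_genes = 0L, genome_length = 5000L)
  gen <- generate_genome_and_annotation(cfg)
  expect_equal(nrow(gen$genes), 0L)
  expect_equal(nrow(gen$truth), 0L)
  expect_equal(Biostrings::width(gen$genome), 5000L)

  cfg2 <- sim_config(seed = 8)
  g1 <- generate_genome_and_annotation(cfg2)
  g2 <- generate_genome_and_annotation(cfg2)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$features, g2$features)

  expect_error(generate_genome_and_annotation(
    sim_config(seed = 1, genome_length = 20000L)), "too short")
})

test_that("structure seed decouples truth from intensity noise", {
  c1 <- sim_config(seed = 21, structure_seed = 99L)
  c2 <- sim_config(seed = 22, structure_seed = 99L)
  g1 <- generate_genome_and_annotation(c1)
  g2 <- generate_genome_and_annotation(c2)
  expect_identical(g1$truth, g2$truth)
  pm <- probe_map_from_design(design_tiling_probes(g1$genome, 25L))
  i1 <- simulate_intensities(g1$truth, pm, c1)
  i2 <- simulate_intensities(g2$truth, pm, c2)
  expect_false(identical(i1$values, i2$values))
})

test_that("planted covering antisense transcripts span their gene's CDS", {
  gen <- generate_genome_and_annotation(sim_config(seed = 9))
  cov <- gen$truth[gen$truth$covering, ]
  expect_gt(nrow(cov), 0L)
  for (i in seq_len(nrow(cov))) {
    g <- gen$genes[gen$genes$gene_id == cov$parent_gene[i], ]
    expect_lte(cov$start[i], g$cds_start)
    expect_gte(cov$end[i], g$cds_end)
    expect_true(cov$strand[i] != g$strand)
  }
  # the mid-meiotic program: vegetative antisense above sense, reversed at 6 h
  mid <- gen$genes$gene_id[gen$genes$class %in%
                             c("mid_meiotic_discrete", "mid_meiotic_utr3")]
  for (gid in mid) {
    s <- gen$truth[!is.na(gen$truth$parent_gene) &
                     gen$truth$parent_gene == gid & gen$truth$covering, ]
    m <- gen$truth[gen$truth$transcript_id == paste0(gid, ".t1"), ]
    expect_gt(s$ab_veg, m$ab_veg)
    expect_gt(m$ab_mei6h, m$ab_veg)
    expect_lt(s$ab_mei6h, s$ab_veg)
  }
})

test_that("forkhead motifs are planted within 200 nt upstream of meiotic TSS", {
  gen <- generate_genome_and_annotation(sim_config(seed = 10))
  fk <- gen$features[gen$features$feature == "forkhead_motif", ]
  expect_gt(nrow(fk), 0L)
  seqs <- as.character(Biostrings::extractAt(
    gen$genome[[1]], IRanges::IRanges(fk$start, fk$end)))
  planted <- ifelse(fk$strand == "+", seqs,
                    vapply(seqs, revcomp_str, character(1)))
  expect_true(all(planted %in% c("GTAAACA", "GTAAATA")))
  hx <- gen$features[gen$features$feature == "internal_hexamer", ]
  hseq <- as.character(Biostrings::extractAt(
    gen$genome[[1]], IRanges::IRanges(hx$start, hx$end)))
  expect_true(all(hseq == "ACGCTC"))
})

test_that("tiling design has the predicted probe count and round-trips", {
  g25 <- Biostrings::DNAStringSet(c(c1 = rdna(25)))
  expect_equal(nrow(design_tiling_probes(g25, 1L)), 2L)
  g124 <- Biostrings::DNAStringSet(c(c1 = rdna(124)))
  expect_equal(nrow(design_tiling_probes(g124, 20L)), 10L)
  expect_warning(design_tiling_probes(
    Biostrings::DNAStringSet(c(c1 = rdna(20))), 5L), "shorter")

  set.seed(30)
  genome <- Biostrings::DNAStringSet(c(chrI = rdna(2000)))
  design <- design_tiling_probes(genome, 25L)
  pm <- map_probes(design, genome)
  src <- pm[match(design$probe_id, pm$probe_id), ]
  expect_equal(src$start, design$start)
  expect_equal(src$strand, design$strand)
})

test_that("intensity model reduces to closed forms in degenerate settings", {
  probes <- data.frame(probe_id = "p1", sequence = NA, chrom = "chrI",
                       strand = "+", start = 101L, unique = TRUE)
  truth <- data.frame(transcript_id = "t1", chrom = "chrI", strand = "+",
                      start = 50L, end = 200L, class = "sense_mRNA",
                      spliced = FALSE, parent_gene = NA, covering = FALSE,
                      ab_veg = 8, stringsAsFactors = FALSE)
  # no affinity spread, no noise, no background: signal is the abundance
  cfg <- sim_config(seed = 3, conditions = "veg", affinity_sigma = 0,
                    noise_cv = 0, background_level = 0)
  im <- simulate_intensities(truth, probes, cfg)
  expect_equal(unname(im$values["p1", "veg"]), 8)

  # zero abundance: expectation equals the background level
  truth0 <- truth; truth0$ab_veg <- 0
  cfg2 <- sim_config(seed = 3, conditions = "veg", background_level = 2)
  many <- vapply(1:200, function(s) {
    cfg2$seed <- s
    simulate_intensities(truth0, probes, cfg2)$values["p1", "veg"]
  }, numeric(1))
  expect_equal(mean(many), 2, tolerance = 0.15)
})

test_that("expected intensity is monotone in transcript abundance", {
  probes <- data.frame(probe_id = "p1", sequence = NA, chrom = "chrI",
                       strand = "+", start = 101L, unique = TRUE)
  truth <- data.frame(transcript_id = "t1", chrom = "chrI", strand = "+",
                      start = 50L, end = 200L, class = "sense_mRNA",
                      spliced = FALSE, parent_gene = NA, covering = FALSE,
                      ab_veg = 1, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 4, conditions = "veg", affinity_sigma = 0,
                    noise_cv = 0)
  vals <- vapply(c(0, 0.5, 2, 8, 32), function(a) {
    truth$ab_veg <- a
    simulate_intensities(truth, probes, cfg)$values["p1", "veg"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
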