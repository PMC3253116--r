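# a normalized signal with two planted transcripts over tiny_genes():
# gA (+, 1001..2500) expressed sense; gB (-, 5001..6800) silent in sense
# but covered by an antisense (+) segment
quantify_fixture <- function(noise = 0, seed = 301) {
  set.seed(seed)
  sig <- toy_signal(function(start, strand) {
    lvl <- 0
    if (strand == "+" && start >= 951 && start + 24 <= 2600) lvl <- 3
    if (strand == "+" && start >= 4801 && start + 24 <= 7000) lvl <- 2
    lvl + if (noise > 0) rnorm(1, 0, noise) else 0
  })
  sig
}

test_that("segment means match a naive summation oracle", {
  sig <- quantify_fixture(noise = 0.5)
  segs <- segment_genome(sig, segmentation_model(), "veg")
  for (i in sample(nrow(segs), min(10, nrow(segs)))) {
    rows <- segs$row_first[i]:segs$row_last[i]
    naive <- sum(sig$values[rows, "veg"]) / length(rows)
    expect_equal(segment_mean(segs[i, ], sig, "veg"), naive,
                 tolerance = 1e-12)
  }
  # hand-sized example: probes {1, 2, 3} average to 2
  s3 <- toy_signal(function(start, strand) 0)
  s3$values[1:3, 1] <- c(1, 2, 3)
  one <- data.frame(row_first = 1L, row_last = 3L)
  expect_equal(segment_mean(one, s3, "veg"), 2)
})

test_that("segments are classified by maximal CDS overlap, one category each", {
  genes <- tiny_genes()
  segs <- data.frame(
    segment_id = c("s1", "s2", "s3", "s4"),
    chrom = "chrI", strand = c("-", "+", "+", "-"),
    start = c(1001L, 3000L, 4801L, 900L),
    end = c(2500L, 3900L, 7000L, 5100L),
    mean_intensity = c(2, 0.1, 2, 1.4),
    row_first = NA, row_last = NA, stringsAsFactors = FALSE)
  ann <- classify_segments(segs, genes)
  # s1: minus-strand segment exactly spanning gA's plus-strand CDS
  expect_equal(ann$category[1], "antisense")
  expect_equal(ann$gene_id[1], "gA")
  # s2: intergenic
  expect_equal(ann$category[2], "non_annotated")
  # s3: plus-strand over gB (minus gene): antisense
  expect_equal(ann$category[3], "antisense")
  expect_equal(ann$gene_id[3], "gB")
  # s4 overlaps gA (1001..2500, same-strandness: segment -, gA +) by 1500
  # and gB (5001..6800, segment -, gB -) by 100: maximal overlap wins
  bf <- function(seg_start, seg_end) {
    ov <- pmin(genes$cds_end, seg_end) - pmax(genes$cds_start, seg_start) + 1
    genes$gene_id[which.max(ov)]
  }
  expect_equal(ann$gene_id[4], bf(900L, 5100L))
  expect_equal(ann$category[4], "antisense")
  # every segment gets exactly one category
  expect_true(all(ann$category %in% c("sense", "antisense", "non_annotated")))
})

test_that("antisense calling respects the threshold, category and monotonicity", {
  genes <- tiny_genes()
  segs <- data.frame(
    segment_id = c("a_low", "a_high", "s_high"),
    chrom = "chrI", strand = c("-", "-", "+"),
    start = c(1001L, 1001L, 1001L), end = c(2500L, 2500L, 2500L),
    mean_intensity = c(0.99, 1.01, 5.0),
    row_first = NA, row_last = NA, stringsAsFactors = FALSE)
  ann <- classify_segments(segs, genes)
  calls <- call_antisense(ann, threshold = 1.0)
  expect_equal(calls$segment_id, "a_high")   # 0.99 misses, sense never calls
  expect_true(all(calls$covers_full_cds))
  # raising the threshold can only shrink the call set
  thresholds <- c(0.5, 1.0, 1.5, 2.0)
  sets <- lapply(thresholds, function(t) call_antisense(ann, t)$segment_id)
  for (i in seq_len(length(sets) - 1L))
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
})

test_that("a segment over two opposite-strand genes yields one call per gene", {
  genes <- gene_models(data.frame(
    gene_id = c("gX", "gY"), chrom = "chrI", strand = c("+", "-"),
    cds_start = c(1001L, 2601L), cds_end = c(2500L, 4000L),
    stringsAsFactors = FALSE))
  seg <- data.frame(segment_id = "s", chrom = "chrI", strand = "-",
                    start = 1001L, end = 2500L, mean_intensity = 2,
                    row_first = NA, row_last = NA, stringsAsFactors = FALSE)
  # minus-strand segment: antisense for gX; a second plus-strand segment
  # spanning both genes is sense for gX and antisense for gY
  seg2 <- data.frame(segment_id = "w", chrom = "chrI", strand = "+",
                     start = 1001L, end = 4000L, mean_intensity = 2,
                     row_first = NA, row_last = NA, stringsAsFactors = FALSE)
  ann <- classify_segments(rbind(seg, seg2), genes)
  calls <- call_antisense(ann, 1.0)
  expect_setequal(paste(calls$segment_id, calls$gene_id),
                  c("s gX", "w gY"))
})

test_that("antisense origin separates discrete units from 3'UTR extensions", {
  sig <- quantify_fixture(noise = 0.15)
  genes <- tiny_genes()
  segs <- segment_genome(sig, segmentation_model(), "veg")
  ann <- classify_segments(segs, genes)
  calls <- call_antisense(ann, 1.0)
  calls <- classify_antisense_origin(calls, segs, genes)
  # the + segment over gB (5001..6800) continues from gA's 3' end region?
  # no: it starts at 4801, well beyond gA's CDS end (2500) -> discrete
  expect_true("gB" %in% calls$gene_id)
  expect_equal(calls$origin[calls$gene_id == "gB"], "discrete_unit")

  # spo6-like: extend the expressed run so it flows out of gA's CDS
  sig2 <- toy_signal(function(start, strand) {
    lvl <- 0
    if (strand == "+" && start >= 951 && start + 24 <= 7000) lvl <- 3
    lvl + rnorm(1, 0, 0.15)
  })
  segs2 <- segment_genome(sig2, segmentation_model(), "veg")
  ann2 <- classify_segments(segs2, genes)
  calls2 <- call_antisense(ann2, 1.0)
  calls2 <- classify_antisense_origin(calls2, segs2, genes)
  expect_true("gB" %in% calls2$gene_id)
  expect_equal(calls2$origin[calls2$gene_id == "gB"], "utr3_extension")
})

test_that("gene strand expression averages CDS probes per strand", {
  genes <- tiny_genes()
  sig <- toy_signal(function(start, strand) {
    if (strand == "+" && start >= 951 && start + 24 <= 2600) 3.0
    else if (strand == "-" && start >= 951 && start + 24 <= 2600) 0.2
    else 0
  })
  g <- gene_strand_expression(genes, sig, "veg")
  expect_equal(g$sense_avg[g$gene_id == "gA"], 3.0)
  expect_equal(g$antisense_avg[g$gene_id == "gA"], 0.2)
  # a gene whose CDS contains no probe on either strand is flagged missing
  genes2 <- rbind(genes, data.frame(gene_id = "tiny", chrom = "chrI",
                                    strand = "+", cds_start = 9990L,
                                    cds_end = 9999L, utr3_end = NA))
  g2 <- gene_strand_expression(genes2, sig, "veg")
  expect_true(is.na(g2$sense_avg[g2$gene_id == "tiny"]))
  expect_equal(g2$n_sense_probes[g2$gene_id == "tiny"], 0L)

  # consistency with segmentation: constant signal over a gene inside one
  # segment gives sense_avg equal to that segment's mean
  segs <- segment_genome(sig, segmentation_model(), "veg")
  seg_of_gA <- segs[segs$strand == "+" & segs$start <= 1001 &
                      segs$end >= 2500, ]
  expect_equal(g$sense_avg[g$gene_id == "gA"],
               seg_of_gA$mean_intensity[1], tolerance = 1e-9)
})

test_that("splicing index separates spliced, unspliced and antisense cases", {
  genes <- gene_models(data.frame(
    gene_id = c("gs", "gu", "ga"), chrom = "chrI", strand = "+",
    cds_start = c(1001L, 4001L, 7001L), cds_end = c(2500L, 5500L, 8500L),
    stringsAsFactors = FALSE))
  exons <- data.frame(gene_id = rep(c("gs", "gu", "ga"), each = 2),
                      start = c(1001L, 1901L, 4001L, 4901L, 7001L, 7901L),
                      end = c(1700L, 2500L, 4700L, 5500L, 7700L, 8500L))
  sig <- toy_signal(function(start, strand) {
    inside <- function(a, b) start >= a && start + 24 <= b
    if (strand == "+") {
      if (inside(1001, 2500)) {
        if (inside(1701, 1900)) return(0)   # spliced: intron empty
        return(3)
      }
      if (inside(4001, 5500)) return(3)     # unspliced: intron = exon
      if (inside(7001, 8500)) return(0.1)   # silent sense
    }
    if (strand == "-" && inside(6900, 8600)) return(3)  # covering antisense
    0
  })
  si <- splicing_index(genes, exons, sig, "veg")
  expect_lt(si$si[si$gene_id == "gs"], -1)
  expect_equal(si$status[si$gene_id == "gs"], "spliced")
  expect_equal(si$si[si$gene_id == "gu"], 0)
  expect_equal(si$status[si$gene_id == "gu"],
               "unspliced_or_antisense_dominated")
  # the antisense-dominated gene: sense-strand SI is flat but the emitted
  # antisense_avg exposes the covering antisense RNA
  expect_equal(si$si[si$gene_id == "ga"], 0)
  expect_gt(si$antisense_avg[si$gene_id == "ga"],
            2 + si$si[si$gene_id == "ga"])
  # no eligible intron probes: flagged not-computable
  exons_tiny <- data.frame(gene_id = "gs", start = c(1001L, 1026L),
                           end = c(1020L, 2500L))
  si2 <- splicing_index(genes[1, ], exons_tiny, sig, "veg")
  expect_equal(si2$status, "not_computable")
})
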