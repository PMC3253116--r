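# shared fixture builders and independent oracles

BASES <- c("A", "C", "G", "T")

rdna <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force exact-match probe placement: scan every position, both strands
brute_force_placements <- function(probe, genome_str) {
  L <- nchar(genome_str)
  k <- nchar(probe)
  n <- L - k + 1L
  if (n < 1L) return(data.frame(strand = character(), start = integer()))
  windows <- substring(genome_str, seq_len(n), seq_len(n) + k - 1L)
  fwd <- which(windows == probe)
  rev <- which(windows == revcomp_str(probe))
  data.frame(strand = c(rep("+", length(fwd)), rep("-", length(rev))),
             start = c(fwd, rev))
}

# exhaustive optimal RSS over all boundary placements, for small n
enum_best_rss <- function(x, k) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  seg_rss <- function(starts, ends) {  # vectors, 1-based inclusive
    su <- cs[ends + 1L] - cs[starts]
    sum(cs2[ends + 1L] - cs2[starts] - su^2 / (ends - starts + 1L))
  }
  if (k == 1L) return(seg_rss(1L, n))
  best <- Inf
  for (cut in utils::combn(seq_len(n - 1L), k - 1L, simplify = FALSE)) {
    rss <- seg_rss(c(1L, cut + 1L), c(cut, n))
    if (rss < best) best <- rss
  }
  best
}

# position-by-position IUPAC matcher, no regex, no Biostrings
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

naive_iupac_hits <- function(seq_str, motif, strand = "+") {
  if (strand == "-") motif <- revcomp_str(motif)  # pattern as seen on +
  sv <- strsplit(seq_str, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  k <- length(mv)
  hits <- integer()
  for (p in seq_len(length(sv) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sv[p + j - 1L] %in% IUPAC_SETS[[mv[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# small two-gene annotation on a 10 kb chromosome, for interval tests
tiny_genes <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gB"), chrom = "chrI", strand = c("+", "-"),
    cds_start = c(1001L, 5001L), cds_end = c(2500L, 6800L),
    stringsAsFactors = FALSE))
}

# hand-built normalized signal: probes every 25 nt on both strands of a
# 10 kb chromosome, with values set by a function(start, strand)
toy_signal <- function(value_fn, L = 10000L, samples = "veg") {
  starts <- seq(1L, L - 24L, by = 25L)
  probes <- rbind(
    data.frame(probe_id = sprintf("p%05d", starts), sequence = NA,
               chrom = "chrI", strand = "+", start = starts, unique = TRUE),
    data.frame(probe_id = sprintf("m%05d", starts), sequence = NA,
               chrom = "chrI", strand = "-", start = starts, unique = TRUE))
  probes <- probes[order(probes$chrom, probes$strand, probes$start), ]
  rownames(probes) <- NULL
  values <- vapply(samples, function(s)
    mapply(value_fn, probes$start, probes$strand), numeric(nrow(probes)))
  values <- matrix(values, ncol = length(samples),
                   dimnames = list(probes$probe_id, samples))
  structure(list(values = values, probes = probes,
                 background = stats::setNames(rep(0, length(samples)), samples),
                 n_background_probes = 0L, n_excluded = 0L),
            class = "normalized_signal")
}

# per-gene expression table with the wide sense_/antisense_ schema
toy_expr_table <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             sense_veg = rnorm(n, 3, 1.5),
             antisense_veg = rnorm(n, 0.3, 0.5),
             sense_mei4h = rnorm(n, 3, 1.5),
             antisense_mei4h = rnorm(n, 0.3, 0.5),
             sense_mei6h = rnorm(n, 3, 1.5),
             antisense_mei6h = rnorm(n, 0.3, 0.5),
             sense_fkh2 = rnorm(n, 3, 1.5),
             antisense_fkh2 = rnorm(n, 0.3, 0.5),
             stringsAsFactors = FALSE)
}
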