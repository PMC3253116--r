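`%||%` <- function(x, y) if (is.null(x)) y else x

PROBE_LEN <- 25L

#' Read a genome from FASTA
#'
#' Chromosome names are truncated at the first whitespace, as is conventional
#' for FASTA headers.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return a [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
  genome
}

#' @rdname read_genome_fasta
#' @param genome a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

validate_genome <- function(genome) {
  if (length(genome) == 0L) stop("genome is empty")
  if (anyDuplicated(names(genome)))
    stop("duplicated chromosome identifiers in genome")
  if (any(Biostrings::width(genome) == 0L)) stop("empty chromosome sequence")
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0))
    stop("genome sequence contains letters outside {A,C,G,T,N}")
  invisible(genome)
}

#' Construct and validate a set of gene models
#'
#' A gene model is the unit over which strand-specific expression is
#' averaged: its CDS span runs from the ATG through the stop codon
#' (introns included), on a declared strand. Coordinates are 1-based,
#' closed.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `cds_start`, `cds_end` and optionally
#'   `utr3_end`.
#' @param exons optional data.frame with columns `gene_id`, `start`, `end`
#'   giving the exon structure of (a subset of) the genes; exons must be
#'   sorted, non-overlapping, and introns are derived as the gaps between
#'   consecutive exons.
#' @return the validated `genes` data.frame (invisibly validates `exons`).
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "strand", "cds_start", "cds_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$cds_start > genes$cds_end)) stop("cds_start must be <= cds_end")
  if (is.null(genes$utr3_end)) genes$utr3_end <- NA_integer_
  if (!is.null(exons)) validate_exons(genes, exons)
  genes
}

validate_exons <- function(genes, exons) {
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start > ex$end)) stop("malformed exon in gene ", gid)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in gene ", gid)
  }
  invisible(exons)
}

#' Derive intron intervals from exon structure
#'
#' @inheritParams gene_models
#' @return data.frame `gene_id`, `start`, `end` of introns (1-based closed);
#'   zero rows when every gene is single-exon.
#' @export
gene_introns <- function(exons) {
  if (is.null(exons) || nrow(exons) == 0L)
    return(data.frame(gene_id = character(), start = integer(), end = integer()))
  out <- lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(gene_id = ex$gene_id[1L],
               start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1L] - 1L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out %||% data.frame(gene_id = character(), start = integer(), end = integer())
}

#' Read / write gene annotation as GFF3
#'
#' Reads `gene` features (the CDS span, ATG through stop) and their `exon`
#' children. Writing emits the same two feature types. GFF3 is 1-based
#' closed, matching the package's internal convention, so no coordinate
#' shift is applied.
#'
#' @param path GFF3 file path.
#' @return list with elements `genes` and `exons` (see [gene_models()]).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gtype <- as.character(gr$type)
  g <- gr[gtype == "gene"]
  ids <- as.character(g$ID %||% g$Name)
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    cds_start = GenomicRanges::start(g),
    cds_end = GenomicRanges::end(g),
    stringsAsFactors = FALSE
  )
  e <- gr[gtype == "exon"]
  exons <- data.frame(
    gene_id = vapply(e$Parent, function(p) as.character(p)[1L], character(1)),
    start = GenomicRanges::start(e),
    end = GenomicRanges::end(e),
    stringsAsFactors = FALSE
  )
  list(genes = gene_models(genes, exons), exons = exons)
}

#' @rdname read_annotation_gff3
#' @param genes,exons annotation tables as returned by [read_annotation_gff3()].
#' @export
write_annotation_gff3 <- function(genes, exons = NULL, path) {
  g <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$cds_start, genes$cds_end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id
  )
  grl <- g
  if (!is.null(exons) && nrow(exons) > 0L) {
    stmap <- stats::setNames(genes$strand, genes$gene_id)
    chmap <- stats::setNames(genes$chrom, genes$gene_id)
    e <- GenomicRanges::GRanges(
      seqnames = chmap[exons$gene_id],
      ranges = IRanges::IRanges(exons$start, exons$end),
      strand = stmap[exons$gene_id],
      type = "exon", ID = NA_character_
    )
    e$Parent <- as.character(exons$gene_id)
    g$Parent <- NA_character_
    grl <- c(g, e)
  }
  rtracklayer::export(grl, path, format = "gff3")
  invisible(path)
}

genes_gr <- function(genes, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$cds_start, genes$cds_end),
    strand = if (stranded) genes$strand else "*"
  )
}

probes_gr <- function(probes, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(probes$start, probes$start + PROBE_LEN - 1L),
    strand = if (stranded) probes$strand else "*"
  )
}

#' Map probe sequences to a genome by exact matching
#'
#' Every 25-nt probe is placed at every position where it matches the
#' genome exactly: on the plus strand where the probe sequence equals the
#' genomic sequence, on the minus strand where it equals the reverse
#' complement. A probe assigned strand *s* reports RNA transcribed from
#' strand *s* (sense signal for genes on *s*); this convention is applied
#' consistently by the simulator and quantification. Probes placed exactly
#' once genome-wide are flagged `unique` and are the only ones used in
#' downstream intensity computations; probes with zero placements are
#' dropped and counted.
#'
#' @param probe_sequences named character vector of 25-nt probe sequences
#'   (names are probe ids), or a design data.frame with columns `probe_id`
#'   and `sequence`.
#' @param genome a `DNAStringSet`.
#' @return a probe map: data.frame `probe_id`, `sequence`, `chrom`,
#'   `strand`, `start`, `unique`, sorted by (chrom, strand, start), with
#'   attributes `n_unmapped` and `unmapped_ids`.
#' @export
map_probes <- function(probe_sequences, genome) {
  validate_genome(genome)
  if (is.data.frame(probe_sequences)) {
    seqs <- stats::setNames(probe_sequences$sequence, probe_sequences$probe_id)
  } else {
    seqs <- probe_sequences
    if (is.null(names(seqs)))
      names(seqs) <- sprintf("probe_%06d", seq_along(seqs))
  }
  bad <- names(seqs)[nchar(seqs) != PROBE_LEN]
  if (length(bad))
    stop("probes not of length 25: ", paste(utils::head(bad, 5L), collapse = ", "))

  pset <- Biostrings::DNAStringSet(seqs)
  clean <- rowSums(Biostrings::alphabetFrequency(pset)[, c("A", "C", "G", "T"), drop = FALSE]) == PROBE_LEN
  placeable <- pset[clean]
  hits <- list()
  if (length(placeable)) {
    pd_fwd <- Biostrings::PDict(placeable)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(placeable))
    for (chrom in names(genome)) {
      subject <- genome[[chrom]]
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") pd_fwd else pd_rev, subject)
        st <- Biostrings::startIndex(m)
        n_hit <- lengths(st)
        idx <- which(n_hit > 0L)
        if (length(idx)) {
          hits[[length(hits) + 1L]] <- data.frame(
            probe_id = rep(names(placeable)[idx], n_hit[idx]),
            chrom = chrom, strand = str,
            start = unlist(st[idx], use.names = FALSE),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  pm <- if (length(hits)) do.call(rbind, hits) else
    data.frame(probe_id = character(), chrom = character(),
               strand = character(), start = integer())
  n_place <- table(pm$probe_id)
  pm$unique <- as.vector(n_place[pm$probe_id]) == 1L
  pm$sequence <- as.character(seqs[pm$probe_id])
  unmapped <- setdiff(names(seqs), pm$probe_id)
  pm <- pm[order(match(pm$chrom, names(genome)), pm$strand, pm$start), ,
           drop = FALSE]
  pm <- pm[, c("probe_id", "sequence", "chrom", "strand", "start", "unique")]
  rownames(pm) <- NULL
  attr(pm, "n_unmapped") <- length(unmapped)
  attr(pm, "unmapped_ids") <- unmapped
  pm
}

#' Build a probe map directly from tiling-design coordinates
#'
#' For probe designs generated by tiling a known genome
#' ([design_tiling_probes()]), every probe's placement is its design
#' position, so the exact-match search can be bypassed. Probes are marked
#' unique; this is appropriate for non-repetitive (e.g. simulated random)
#' genomes, where 25-mer collisions are vanishingly rare. Use
#' [map_probes()] whenever repeat content matters.
#'
#' @param design data.frame with `probe_id`, `sequence`, `chrom`, `strand`,
#'   `start` (as produced by [design_tiling_probes()]).
#' @return a probe map in the same format as [map_probes()].
#' @export
probe_map_from_design <- function(design) {
  pm <- design[, c("probe_id", "sequence", "chrom", "strand", "start")]
  pm$unique <- TRUE
  pm <- pm[order(pm$chrom, pm$strand, pm$start), , drop = FALSE]
  rownames(pm) <- NULL
  attr(pm, "n_unmapped") <- 0L
  attr(pm, "unmapped_ids") <- character()
  pm
}

#' Read / write a probe map as TSV
#' @param path TSV path.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  pm$unique <- as.logical(pm$unique)
  pm
}

#' @rdname read_probe_map
#' @param probes probe map data.frame.
#' @export
write_probe_map <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a raw intensity matrix
#'
#' Raw linear fluorescence for every designed probe (rows) in every sample
#' (columns). Exactly one sample must be a genomic-DNA hybridization
#' channel; it carries the probe-effect reference used by
#' [normalize_to_gdna()].
#'
#' @param values numeric matrix, probes x samples, strictly positive, with
#'   rownames = probe ids and colnames = sample names.
#' @param samples data.frame with columns `sample`, `condition`, `channel`
#'   (`"RNA"` or `"gDNA"`), one row per column of `values`.
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values <= 0)) stop("intensity values must be strictly positive")
  if (!setequal(colnames(values), samples$sample))
    stop("sample metadata does not match matrix columns")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  if (sum(samples$channel == "gDNA") != 1L)
    stop("exactly one gDNA-channel sample is required")
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("<intensity_matrix> ", nrow(x$values), " probes x ",
      ncol(x$values), " samples (",
      sum(x$samples$channel == "RNA"), " RNA + ",
      sum(x$samples$channel == "gDNA"), " gDNA)\n", sep = "")
  invisible(x)
}

#' @rdname intensity_matrix
#' @param im an `intensity_matrix`.
#' @param path base path; writes `<path>` as TSV with a `probe_id` column
#'   and one column per sample, and `<path>.samples.tsv` with the metadata.
#' @export
write_intensity_matrix <- function(im, path) {
  df <- data.frame(probe_id = rownames(im$values), im$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(im$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname intensity_matrix
#' @export
read_intensity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$probe_id
  samples <- utils::read.delim(paste0(path, ".samples.tsv"),
                               stringsAsFactors = FALSE)
  intensity_matrix(values, samples)
}
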