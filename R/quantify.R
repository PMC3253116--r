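#' Recompute segment mean intensities from the probe signal
#'
#' The mean of a segment is the sum of the signal of every probe in the
#' segment divided by the number of probes — recomputable at any time from
#' the normalized signal, which this helper does (used to verify stored
#' `mean_intensity` values and to re-quantify segments in other samples).
#'
#' @param segments segment table from [segment_genome()].
#' @param signal the `normalized_signal` the segments were built on.
#' @param sample sample column to average.
#' @return numeric vector of means, one per segment row.
#' @export
segment_mean <- function(segments, signal,
                         sample = attr(segments, "sample")) {
  vapply(seq_len(nrow(segments)), function(i) {
    mean(signal$values[segments$row_first[i]:segments$row_last[i], sample])
  }, numeric(1))
}

#' Classify segments against the gene annotation
#'
#' Each segment is assigned the gene whose CDS it overlaps the most
#' (requiring at least `min_overlap` nt): same-strand overlap makes a
#' `sense` segment, opposite-strand an `antisense` segment, and segments
#' without a qualifying CDS overlap are `non_annotated`. Because a probe
#' can report sense for one gene and antisense for an overlapping
#' opposite-strand gene, the full table of qualifying (segment, gene)
#' pairs is kept in the `pairs` attribute; the per-segment category uses
#' the maximal overlap.
#'
#' @param segments segment table from [segment_genome()].
#' @param genes gene annotation ([gene_models()]).
#' @param min_overlap minimum CDS overlap in nt (default 50, suppressing
#'   boundary-probe bleed).
#' @return `segments` with added columns `category`, `gene_id`,
#'   `overlap_frac` (fraction of the assigned gene's CDS covered), and
#'   attribute `pairs` (data.frame `segment_id`, `gene_id`, `relation`,
#'   `overlap`, `overlap_frac`, `mean_intensity`, `covers_full_cds`).
#' @export
classify_segments <- function(segments, genes, min_overlap = 50L) {
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start, segments$end))
  pairs <- data.frame(segment_id = character(), gene_id = character(),
                      relation = character(), overlap = integer(),
                      overlap_frac = numeric(), mean_intensity = numeric(),
                      covers_full_cds = logical(), stringsAsFactors = FALSE)
  if (nrow(genes) > 0L) {
    ggr <- genes_gr(genes, stranded = FALSE)
    ov <- GenomicRanges::findOverlaps(seg_gr, ggr, minoverlap = min_overlap)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(seg_gr)[qh], IRanges::ranges(ggr)[sh]))
      pairs <- data.frame(
        segment_id = segments$segment_id[qh],
        gene_id = genes$gene_id[sh],
        relation = ifelse(segments$strand[qh] == genes$strand[sh],
                          "sense", "antisense"),
        overlap = w,
        overlap_frac = w / (genes$cds_end[sh] - genes$cds_start[sh] + 1L),
        mean_intensity = segments$mean_intensity[qh],
        covers_full_cds = segments$start[qh] <= genes$cds_start[sh] &
          segments$end[qh] >= genes$cds_end[sh],
        stringsAsFactors = FALSE)
    }
  }
  segments$category <- "non_annotated"
  segments$gene_id <- NA_character_
  segments$overlap_frac <- NA_real_
  if (nrow(pairs)) {
    ord <- order(match(pairs$segment_id, segments$segment_id), -pairs$overlap)
    best <- pairs[ord, ][!duplicated(pairs$segment_id[ord]), ]
    i <- match(best$segment_id, segments$segment_id)
    segments$category[i] <- ifelse(best$relation == "sense", "sense", "antisense")
    segments$gene_id[i] <- best$gene_id
    segments$overlap_frac[i] <- best$overlap_frac
  }
  attr(segments, "pairs") <- pairs
  segments
}

#' Call antisense RNAs from classified segments
#'
#' An antisense RNA is an antisense-relation (segment, gene) pair whose
#' segment mean intensity exceeds the calling threshold (default 1.0 on
#' the normalized log2 scale). One call is made per (gene, segment) pair,
#' so a single segment covering two opposite-strand genes yields two
#' calls.
#'
#' @param seg_ann output of [classify_segments()].
#' @param threshold calling threshold on the mean log2 intensity.
#' @return data.frame `gene_id`, `segment_id`, `mean_intensity`,
#'   `covers_full_cds`, `chrom`, `strand`, `origin_pos` (genomic position
#'   of the antisense segment's 5' end), `origin` (filled by
#'   [classify_antisense_origin()], `NA` here).
#' @export
call_antisense <- function(seg_ann, threshold = 1.0) {
  pairs <- attr(seg_ann, "pairs")
  if (is.null(pairs))
    stop("seg_ann must come from classify_segments()")
  hit <- pairs[pairs$relation == "antisense" &
                 pairs$mean_intensity > threshold, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(data.frame(gene_id = character(), segment_id = character(),
                      mean_intensity = numeric(), covers_full_cds = logical(),
                      chrom = character(), strand = character(),
                      origin_pos = integer(), origin = character(),
                      stringsAsFactors = FALSE))
  i <- match(hit$segment_id, seg_ann$segment_id)
  calls <- data.frame(
    gene_id = hit$gene_id,
    segment_id = hit$segment_id,
    mean_intensity = hit$mean_intensity,
    covers_full_cds = hit$covers_full_cds,
    chrom = seg_ann$chrom[i],
    strand = seg_ann$strand[i],
    origin_pos = ifelse(seg_ann$strand[i] == "+",
                        seg_ann$start[i], seg_ann$end[i]),
    origin = NA_character_,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Classify the origin of called antisense RNAs
#'
#' Distinguishes the two observed antisense architectures. An antisense
#' RNA is a `utr3_extension` when its segment is part of a continuous run
#' of expressed signal (segment means above `expressed_min`, gaps at most
#' `gap_tolerance` nt) that also covers the CDS of a same-strand gene
#' lying upstream in the direction of transcription — i.e. the antisense
#' RNA is the unusually long 3'UTR of a convergent neighbor. It is a
#' `discrete_unit` when its expressed run touches no same-strand CDS
#' (flanked by low-intensity segments on both sides). Anything else is
#' `unclassified`.
#'
#' @param calls output of [call_antisense()].
#' @param segments the full segment table for the sample (all strands).
#' @param genes gene annotation.
#' @param gap_tolerance maximum unexpressed gap (nt) across which signal
#'   is still considered continuous.
#' @param expressed_min mean log2 intensity above which a segment counts
#'   as expressed.
#' @param min_overlap CDS overlap (nt) for a gene to count as part of the
#'   expressed run.
#' @return `calls` with the `origin` column filled.
#' @export
classify_antisense_origin <- function(calls, segments, genes,
                                      gap_tolerance = 100L,
                                      expressed_min = 0.5,
                                      min_overlap = 50L) {
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    seg <- segments[segments$segment_id == calls$segment_id[i], ]
    s <- seg$strand
    expressed <- segments[segments$chrom == seg$chrom &
                            segments$strand == s &
                            segments$mean_intensity > expressed_min, ,
                          drop = FALSE]
    expressed <- expressed[order(expressed$start), , drop = FALSE]
    if (nrow(expressed) == 0L) { calls$origin[i] <- "unclassified"; next }
    gap_new <- c(TRUE, expressed$start[-1L] - expressed$end[-nrow(expressed)] - 1L >
                   gap_tolerance)
    block_id <- cumsum(gap_new)
    me <- which(expressed$segment_id == seg$segment_id)
    if (length(me) == 0L) { calls$origin[i] <- "unclassified"; next }
    in_block <- block_id == block_id[me]
    bs <- min(expressed$start[in_block]); be <- max(expressed$end[in_block])
    g0 <- genes[genes$gene_id == calls$gene_id[i], ]
    cand <- genes[genes$strand == s & genes$chrom == seg$chrom &
                    pmin(genes$cds_end, be) - pmax(genes$cds_start, bs) + 1L >=
                    min_overlap, , drop = FALSE]
    cand <- cand[cand$gene_id != calls$gene_id[i], , drop = FALSE]
    if (nrow(cand) == 0L) {
      calls$origin[i] <- "discrete_unit"
    } else {
      upstream <- if (s == "+")
        cand$cds_start < g0$cds_start & cand$cds_end < g0$cds_end
      else
        cand$cds_start > g0$cds_start & cand$cds_end > g0$cds_end
      calls$origin[i] <- if (any(upstream)) "utr3_extension" else "unclassified"
    }
  }
  calls
}

#' Per-gene strand-specific average expression
#'
#' For every gene, averages the normalized log2 intensity of the unique
#' probes lying fully within the CDS span (ATG through stop codon,
#' introns included by default): probes on the gene's strand give
#' `sense_avg`, probes on the opposite strand `antisense_avg`. Genes
#' without a probe on a strand get `NA` there (missing, not zero) and are
#' excluded from downstream medians. Because a probe inside two
#' overlapping opposite-strand genes contributes sense to one and
#' antisense to the other, overlapping annotation is handled naturally.
#'
#' @param genes gene annotation ([gene_models()]).
#' @param signal a `normalized_signal`.
#' @param sample sample column to average.
#' @param include_introns if `FALSE`, probes overlapping an intron
#'   (derived from `exons`) are excluded from the averages.
#' @param exons exon table, required when `include_introns = FALSE`.
#' @return data.frame `gene_id`, `sample`, `sense_avg`, `antisense_avg`,
#'   `n_sense_probes`, `n_antisense_probes`.
#' @export
gene_strand_expression <- function(genes, signal,
                                   sample = colnames(signal$values)[1L],
                                   include_introns = TRUE, exons = NULL) {
  stopifnot(inherits(signal, "normalized_signal"))
  probes <- signal$probes
  pgr <- probes_gr(probes, stranded = FALSE)
  ggr <- genes_gr(genes, stranded = FALSE)
  keep <- rep(TRUE, nrow(probes))
  if (!include_introns) {
    if (is.null(exons)) stop("exons required when include_introns = FALSE")
    intr <- gene_introns(exons)
    if (nrow(intr) > 0L) {
      chmap <- stats::setNames(genes$chrom, genes$gene_id)
      igr <- GenomicRanges::GRanges(chmap[intr$gene_id],
                                    IRanges::IRanges(intr$start, intr$end))
      keep <- GenomicRanges::countOverlaps(pgr, igr) == 0L
    }
  }
  ov <- GenomicRanges::findOverlaps(pgr, ggr, type = "within")
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  use <- keep[qh]
  qh <- qh[use]; sh <- sh[use]
  is_sense <- probes$strand[qh] == genes$strand[sh]
  v <- signal$values[, sample][qh]
  agg <- function(sel) {
    s <- rowsum(cbind(v[sel], 1), group = sh[sel])
    data.frame(gi = as.integer(rownames(s)), avg = s[, 1L] / s[, 2L],
               n = as.integer(s[, 2L]))
  }
  sa <- agg(is_sense); aa <- agg(!is_sense)
  out <- data.frame(gene_id = genes$gene_id, sample = sample,
                    sense_avg = NA_real_, antisense_avg = NA_real_,
                    n_sense_probes = 0L, n_antisense_probes = 0L,
                    stringsAsFactors = FALSE)
  out$sense_avg[sa$gi] <- sa$avg; out$n_sense_probes[sa$gi] <- sa$n
  out$antisense_avg[aa$gi] <- aa$avg; out$n_antisense_probes[aa$gi] <- aa$n
  out
}

#' Per-gene expression for several samples, in wide form
#'
#' Convenience wrapper over [gene_strand_expression()] producing one row
#' per gene with `sense_<sample>` and `antisense_<sample>` columns — the
#' schema used for gene-level analysis tables and their TSV form.
#'
#' @inheritParams gene_strand_expression
#' @param samples character vector of sample columns.
#' @export
gene_expression_table <- function(genes, signal,
                                  samples = colnames(signal$values),
                                  include_introns = TRUE, exons = NULL) {
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (s in samples) {
    g <- gene_strand_expression(genes, signal, s, include_introns, exons)
    out[[paste0("sense_", s)]] <- g$sense_avg
    out[[paste0("antisense_", s)]] <- g$antisense_avg
  }
  out
}

#' Read / write a per-gene expression table as TSV
#'
#' The schema is `gene_id` plus paired `sense_<sample>` /
#' `antisense_<sample>` columns, mirroring published per-gene
#' sense/antisense supplementary tables so such tables can be ingested
#' directly.
#'
#' @param path TSV path.
#' @export
read_gene_expression_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_gene_expression_table
#' @param table wide per-gene expression table.
#' @export
write_gene_expression_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one sample's per-gene expression from a wide table
#' @param table wide table ([gene_expression_table()]).
#' @param sample sample name.
#' @return data.frame `gene_id`, `sense_avg`, `antisense_avg`.
#' @export
gse_sample <- function(table, sample) {
  data.frame(gene_id = table$gene_id,
             sense_avg = table[[paste0("sense_", sample)]],
             antisense_avg = table[[paste0("antisense_", sample)]],
             stringsAsFactors = FALSE)
}

#' Intron/exon splicing index
#'
#' For each gene with at least one intron carrying a unique sense-strand
#' probe fully inside it, `SI = mean(sense intron probes) - mean(sense
#' exon probes)` in log2 units. Spliced transcripts deplete intron
#' signal, so SI below `-delta` is reported as `spliced`; SI near 0 means
#' either an unspliced transcript or a covering antisense RNA dominating
#' both intron and exon probes — the gene's `antisense_avg` is emitted
#' alongside so the two cases can be told apart (a strand-aware check
#' that a simple sense-strand index cannot make on its own).
#'
#' @param genes,exons annotation tables.
#' @param signal a `normalized_signal`.
#' @param sample sample column.
#' @param delta log2 depletion below which a gene is called spliced.
#' @return data.frame `gene_id`, `si`, `n_intron_probes`,
#'   `n_exon_probes`, `antisense_avg`, `status` (`spliced`,
#'   `unspliced_or_antisense_dominated`, `not_computable`).
#' @export
splicing_index <- function(genes, exons, signal,
                           sample = colnames(signal$values)[1L],
                           delta = 1.0) {
  intr <- gene_introns(exons)
  gids <- intersect(unique(intr$gene_id), genes$gene_id)
  probes <- signal$probes
  vals <- signal$values[, sample]
  gexp <- gene_strand_expression(genes, signal, sample)
  out <- data.frame(gene_id = gids, si = NA_real_, n_intron_probes = 0L,
                    n_exon_probes = 0L, antisense_avg = NA_real_,
                    status = "not_computable", stringsAsFactors = FALSE)
  for (i in seq_along(gids)) {
    g <- genes[genes$gene_id == gids[i], ]
    on_strand <- probes$chrom == g$chrom & probes$strand == g$strand
    within <- function(iv) {
      hit <- rep(FALSE, nrow(probes))
      for (j in seq_len(nrow(iv)))
        hit <- hit | (probes$start >= iv$start[j] &
                        probes$start + PROBE_LEN - 1L <= iv$end[j])
      hit
    }
    ex <- exons[exons$gene_id == gids[i], , drop = FALSE]
    ii <- intr[intr$gene_id == gids[i], , drop = FALSE]
    in_i <- on_strand & within(ii)
    in_e <- on_strand & within(ex)
    out$n_intron_probes[i] <- sum(in_i)
    out$n_exon_probes[i] <- sum(in_e)
    out$antisense_avg[i] <- gexp$antisense_avg[gexp$gene_id == gids[i]]
    if (sum(in_i) >= 1L && sum(in_e) >= 1L) {
      out$si[i] <- mean(vals[in_i]) - mean(vals[in_e])
      out$status[i] <- if (out$si[i] < -delta) "spliced"
        else "unspliced_or_antisense_dominated"
    }
  }
  out
}
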