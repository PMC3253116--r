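#' Normalize RNA-channel intensities against the genomic-DNA channel
#'
#' Two-step probe-effect and background correction. For each uniquely
#' mapping probe p and RNA sample c, the probe-effect-corrected ratio is
#' `r[p,c] = log2(rna[p,c] / gdna[p])`; since every probe hybridizes the
#' same DNA copy number in the gDNA channel, dividing by it cancels the
#' probe's sequence-dependent hybridization efficiency. The per-sample
#' background offset `b[c]` is then the median of `r[p,c]` over unique
#' probes whose 25-nt footprint overlaps no annotated CDS on either
#' strand, and the normalized signal is `r[p,c] - b[c]`, anchoring
#' untranscribed regions at 0.
#'
#' The output is exactly invariant to a global rescaling of any RNA
#' sample (the shift is absorbed into `b[c]`).
#'
#' @param rna an [intensity_matrix()] containing the RNA samples and one
#'   gDNA-channel sample (or only RNA samples if `gdna` is supplied).
#' @param gdna optional named numeric vector of gDNA intensities per
#'   probe id; defaults to the gDNA-channel column of `rna`.
#' @param probes probe map from [map_probes()]; only `unique = TRUE`
#'   probes are retained.
#' @param genes gene annotation ([gene_models()]) supplying CDS spans for
#'   the background probe set.
#' @param background_probes optional character vector of probe ids to use
#'   as the background set, overriding the non-CDS rule (required when no
#'   probe lies outside all CDS).
#' @return a `normalized_signal`: list with `values` (matrix, unique
#'   probes x RNA samples, log2), `probes` (the retained probe rows,
#'   sorted by chrom, strand, start), `background` (named per-sample
#'   offsets `b[c]`), `n_background_probes`, and `n_excluded`
#'   (nonpositive-gDNA probes dropped).
#' @export
normalize_to_gdna <- function(rna, gdna = NULL, probes, genes,
                              background_probes = NULL) {
  stopifnot(inherits(rna, "intensity_matrix"))
  if (is.null(gdna)) {
    gcol <- rna$samples$sample[rna$samples$channel == "gDNA"]
    if (length(gcol) != 1L)
      stop("no gDNA-channel sample in the intensity matrix; supply `gdna`")
    gdna <- rna$values[, gcol]
  }
  rna_cols <- rna$samples$sample[rna$samples$channel == "RNA"]
  up <- probes[probes$unique, , drop = FALSE]
  up <- up[order(up$chrom, up$strand, up$start), , drop = FALSE]
  up <- up[up$probe_id %in% rownames(rna$values), , drop = FALSE]
  g <- gdna[up$probe_id]
  bad <- !is.finite(g) | g <= 0
  n_excluded <- sum(bad)
  if (n_excluded > 0L) {
    warning(n_excluded, " probes with zero/negative gDNA intensity excluded")
    up <- up[!bad, , drop = FALSE]
    g <- g[!bad]
  }
  if (nrow(up) == 0L) stop("no usable unique probes")
  r <- log2(rna$values[up$probe_id, rna_cols, drop = FALSE] / g)

  if (is.null(background_probes)) {
    if (nrow(genes) > 0L) {
      ov <- GenomicRanges::countOverlaps(probes_gr(up, stranded = FALSE),
                                         genes_gr(genes, stranded = FALSE))
      background_probes <- up$probe_id[ov == 0L]
    } else background_probes <- up$probe_id
  }
  bg_idx <- match(intersect(background_probes, up$probe_id), up$probe_id)
  if (length(bg_idx) == 0L)
    stop("no probes outside annotated CDS available for background ",
         "correction; supply `background_probes` explicitly")
  b <- apply(r[bg_idx, , drop = FALSE], 2L, stats::median)
  values <- sweep(r, 2L, b)
  rownames(up) <- NULL
  structure(list(values = values, probes = up, background = b,
                 n_background_probes = length(bg_idx),
                 n_excluded = n_excluded),
            class = "normalized_signal")
}

#' @export
print.normalized_signal <- function(x, ...) {
  cat("<normalized_signal> ", nrow(x$values), " unique probes x ",
      ncol(x$values), " RNA samples; ", x$n_background_probes,
      " background probes\n", sep = "")
  invisible(x)
}

#' Write the per-sample normalization report as JSON
#' @param signal a `normalized_signal`.
#' @param path output path.
#' @export
write_normalization_report <- function(signal, path) {
  jsonlite::write_json(
    list(background_offset = as.list(signal$background),
         n_background_probes = signal$n_background_probes,
         n_excluded_probes = signal$n_excluded,
         n_unique_probes = nrow(signal$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
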