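#' Run the full analysis pipeline
#'
#' `simulate` mode generates a synthetic study from `config` (genome,
#' annotation, tiling design, RNA + gDNA intensities), then runs
#' normalization, segmentation of the vegetative sample, segment
#' classification, antisense calling with origin classification,
#' per-gene strand expression for every RNA condition, the gene-level
#' analysis statistics, forkhead-motif scanning with proximity analysis,
#' and a truth-vs-inferred recovery report. `table` mode starts from a
#' wide per-gene expression table (see [gene_expression_table()] /
#' [read_gene_expression_table()]) and runs only the gene-level analysis
#' operations.
#'
#' @param config a [sim_config()] (simulate mode).
#' @param mode `"simulate"` or `"table"`.
#' @param table wide per-gene expression table (table mode), with
#'   `sense_<s>` / `antisense_<s>` columns for samples among veg, mei4h,
#'   mei6h, fkh2.
#' @param an_cfg an [analysis_config()].
#' @param seg_model a [segmentation_model()].
#' @param map_mode `"exact"` re-maps probe sequences to the genome with
#'   [map_probes()]; `"design"` trusts the tiling-design coordinates
#'   ([probe_map_from_design()], appropriate for non-repetitive
#'   simulated genomes and much faster).
#' @param segment_sample RNA sample to segment (default `"veg"`).
#' @param motif IUPAC motif for the proximity analysis.
#' @param out_dir optional output directory; when given, all tables plus
#'   a manifest are written there.
#' @return a result bundle (list); see the vignette for a walk-through.
#' @export
run_pipeline <- function(config = sim_config(), mode = c("simulate", "table"),
                         table = NULL, an_cfg = analysis_config(),
                         seg_model = segmentation_model(),
                         map_mode = c("exact", "design"),
                         segment_sample = "veg", motif = "GTAAAYA",
                         out_dir = NULL) {
  mode <- match.arg(mode)
  map_mode <- match.arg(map_mode)
  if (mode == "table") {
    if (is.null(table)) stop("table mode requires `table`")
    res <- list(mode = mode, expr = table,
                analysis = analyze_expression_table(table, an_cfg))
    if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
    return(res)
  }

  gen <- generate_genome_and_annotation(config)
  design <- design_tiling_probes(gen$genome, config$probe_step)
  probes <- if (map_mode == "exact") map_probes(design, gen$genome)
    else probe_map_from_design(design)
  im <- simulate_intensities(gen$truth, probes, config)
  signal <- normalize_to_gdna(im, probes = probes, genes = gen$genes)

  segs <- NULL; seg_ann <- NULL; calls <- NULL
  if (segment_sample %in% colnames(signal$values)) {
    segs <- segment_genome(signal, seg_model, segment_sample)
    seg_ann <- classify_segments(segs, gen$genes)
    calls <- call_antisense(seg_ann, an_cfg$antisense_call_threshold)
    calls <- classify_antisense_origin(calls, segs, gen$genes)
  }

  expr <- gene_expression_table(
    gen$genes, signal,
    samples = intersect(config$conditions, colnames(signal$values)))
  analysis <- analyze_expression_table(expr, an_cfg)

  mid_ids <- gen$genes$gene_id[gen$genes$class %in%
                                 c("mid_meiotic_discrete", "mid_meiotic_utr3")]
  universe <- expr$gene_id[!is.na(expr$sense_veg) & !is.na(expr$antisense_veg)]
  analysis$enrichment_mid_meiotic <- if (length(universe))
    hypergeometric_enrichment(analysis$high_antisense_low_sense, mid_ids,
                              universe) else NULL

  hits <- scan_iupac(gen$genome, motif)
  motif_res <- list(hits = hits)
  if (!is.null(calls) && nrow(calls) > 0L)
    motif_res$proximity_calls <- antisense_near_motif(calls, hits)
  new_truth <- truth_antisense_origins(gen, "new_antisense")
  if (nrow(new_truth) > 0L)
    motif_res$proximity_new_truth <- antisense_near_motif(new_truth, hits)

  res <- list(mode = mode, config = config, gen = gen, design = design,
              probes = probes, intensities = im, signal = signal,
              segments = segs, seg_ann = seg_ann, antisense_calls = calls,
              expr = expr, analysis = analysis, motif = motif_res)
  res$report <- pipeline_recovery_report(res)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# gene-level analysis shared by simulate and table modes; uses whichever
# of the four standard conditions the table carries
analyze_expression_table <- function(expr, an_cfg = analysis_config()) {
  have <- function(s) paste0("sense_", s) %in% names(expr)
  out <- list()
  if (have("veg")) {
    veg <- gse_sample(expr, "veg")
    out$high_antisense_low_sense <- select_high_antisense_low_sense(veg, an_cfg)
    out$n_high_antisense_low_sense <- length(out$high_antisense_low_sense)
    out$median_sense_veg <- stats::median(veg$sense_avg, na.rm = TRUE)
    out$median_antisense_veg <- stats::median(veg$antisense_avg, na.rm = TRUE)
  }
  if (have("veg") && have("fkh2")) {
    out$fkh2_derepressed <- differential_sense(gse_sample(expr, "fkh2"),
                                               gse_sample(expr, "veg"),
                                               an_cfg$differential_delta)
    out$n_fkh2_derepressed <- length(out$fkh2_derepressed)
  }
  if (have("veg") && have("mei6h")) {
    veg <- gse_sample(expr, "veg"); m6 <- gse_sample(expr, "mei6h")
    out$new_antisense <- select_new_antisense(veg, m6, an_cfg)
    out$n_new_antisense <- length(out$new_antisense)
    out$delta_correlation_veg_6h <- delta_correlation(veg, m6)
    if (length(out$new_antisense) >= 3L)
      out$delta_correlation_new_antisense <-
        tryCatch(delta_correlation(veg, m6, out$new_antisense),
                 error = function(e) NA_real_)
  }
  if (have("veg") && have("mei4h") && have("mei6h")) {
    out$induction <- meiotic_induction_status(
      gse_sample(expr, "veg"), gse_sample(expr, "mei4h"),
      gse_sample(expr, "mei6h"))
    sel <- out$high_antisense_low_sense
    st <- out$induction[match(sel, out$induction$gene_id), ]
    out$n_group_not_induced <- sum(!st$induced, na.rm = TRUE)
  }
  out
}

# 5' origins of planted antisense transcripts for one generator class
truth_antisense_origins <- function(gen, gene_class) {
  gids <- gen$genes$gene_id[gen$genes$class == gene_class]
  tx <- gen$truth[gen$truth$parent_gene %in% gids &
                    gen$truth$class %in%
                    c("antisense_discrete", "antisense_utr3_extension",
                      "divergent_internal_antisense"), , drop = FALSE]
  data.frame(gene_id = tx$parent_gene, chrom = tx$chrom, strand = tx$strand,
             origin_pos = ifelse(tx$strand == "+", tx$start, tx$end),
             stringsAsFactors = FALSE)
}

#' Truth-vs-inferred recovery report for a simulate-mode run
#'
#' Summarizes how well the pipeline recovered the planted structure:
#' per-probe category accuracy (expressed/background state and
#' sense/antisense/non-annotated label of each probe's segment versus the
#' truth program), antisense origin-class accuracy over the planted
#' discrete and 3'UTR-extension architectures, the recovered log2 fold
#' change of the planted 2-fold class, and the recovered sense-antisense
#' delta correlation of the planted correlated-change class.
#'
#' @param res a simulate-mode [run_pipeline()] result.
#' @return list of recovery metrics (`NA` where the corresponding
#'   architecture was not planted or the stage was not run).
#' @export
pipeline_recovery_report <- function(res) {
  out <- list(n_antisense_calls = if (!is.null(res$antisense_calls))
    nrow(res$antisense_calls) else NA_integer_)
  gen <- res$gen; config <- res$config

  if (!is.null(res$segments)) {
    out$probe_category_accuracy <- probe_category_accuracy(res)
    calls <- res$antisense_calls
    cls <- gen$genes$class[match(calls$gene_id, gen$genes$gene_id)]
    expected <- ifelse(cls %in% c("mid_meiotic_discrete", "new_antisense",
                                  "correlated_change"), "discrete_unit",
                       ifelse(cls == "mid_meiotic_utr3", "utr3_extension",
                              NA_character_))
    ok <- !is.na(expected)
    out$origin_accuracy <- if (any(ok)) mean(calls$origin[ok] == expected[ok])
      else NA_real_
    out$n_origin_evaluated <- sum(ok)
  }

  fc <- gen$genes$gene_id[gen$genes$class == "fold_change"]
  if (length(fc) && all(c("sense_veg", "sense_mei4h") %in% names(res$expr))) {
    i <- match(fc, res$expr$gene_id)
    out$fold_change_log2 <- mean(res$expr$sense_mei4h[i] - res$expr$sense_veg[i],
                                 na.rm = TRUE)
    out$fold_change_planted_log2 <-
      log2(config$levels$fold_change_sense[["mei4h"]] /
             config$levels$fold_change_sense[["veg"]])
  }

  pd <- gen$planted_delta
  if (!is.null(pd) && nrow(pd) >= 3L &&
      all(c("sense_mei6h", "antisense_mei6h") %in% names(res$expr))) {
    out$delta_correlation_planted <- delta_correlation(
      gse_sample(res$expr, "veg"), gse_sample(res$expr, "mei6h"),
      genes = pd$gene_id)
    out$delta_correlation_target <- config$delta_rho
  }
  out
}

# Per-probe truth labels vs segment-derived labels on the segmented
# sample. The truth label is what classification would produce under
# perfect boundary recovery: expressed truth transcripts (abundance above
# `truth_abundance_min` in the segmented condition) are merged per strand
# into pseudo-segments, those are classified against the annotation by
# the same maximal-CDS-overlap rule, and every probe inside inherits the
# label; probes outside are background. Inferred labels come from the
# actual segments (expressed when the mean exceeds the antisense-calling
# threshold). The reported accuracy therefore reflects only boundary and
# thresholding errors.
probe_category_accuracy <- function(res, truth_abundance_min = 1.0) {
  gen <- res$gen
  probes <- res$signal$probes
  sample <- attr(res$segments, "sample")
  ab_col <- paste0("ab_", sample)
  n <- nrow(probes)
  truth_lab <- rep("background", n)
  tx <- gen$truth[gen$truth[[ab_col]] > truth_abundance_min, , drop = FALSE]
  if (nrow(tx)) {
    tgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand))
    pseudo <- data.frame(
      segment_id = sprintf("truth%04d", seq_along(tgr)),
      chrom = as.character(GenomicRanges::seqnames(tgr)),
      strand = as.character(GenomicRanges::strand(tgr)),
      start = GenomicRanges::start(tgr), end = GenomicRanges::end(tgr),
      mean_intensity = Inf, stringsAsFactors = FALSE)
    pseudo <- classify_segments(pseudo, gen$genes)
    ov <- GenomicRanges::findOverlaps(
      probes_gr(probes),
      GenomicRanges::GRanges(pseudo$chrom,
                             IRanges::IRanges(pseudo$start, pseudo$end),
                             strand = pseudo$strand))
    truth_lab[S4Vectors::queryHits(ov)] <-
      pseudo$category[S4Vectors::subjectHits(ov)]
  }
  seg <- res$seg_ann
  inf_lab <- rep("background", n)
  for (i in seq_len(nrow(seg))) {
    if (seg$mean_intensity[i] > 1.0)
      inf_lab[seg$row_first[i]:seg$row_last[i]] <- seg$category[i]
  }
  mean(inf_lab == truth_lab)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$expr))
    write_gene_expression_table(res$expr, p("gene_expression.tsv"))
  if (res$mode == "simulate") {
    write_genome_fasta(res$gen$genome, p("genome.fa"))
    write_annotation_gff3(res$gen$genes, res$gen$exons, p("annotation.gff3"))
    write_probe_map(res$probes, p("probe_map.tsv"))
    write_intensity_matrix(res$intensities, p("intensities.tsv"))
    utils::write.table(res$gen$truth, p("truth_transcripts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$gen$features, p("truth_features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_normalization_report(res$signal, p("normalization.json"))
    if (!is.null(res$segments)) {
      write_segments_bed(res$seg_ann, p("segments.bed"))
      utils::write.table(res$antisense_calls, p("antisense_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$motif$hits))
      write_motif_bed(res$motif$hits, p("motif_hits.bed"))
    jsonlite::write_json(res$report, p("recovery_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  an <- res$analysis
  an$induction <- NULL
  manifest <- list(
    package = "astiler",
    version = as.character(utils::packageVersion("astiler")),
    mode = res$mode,
    seed = if (!is.null(res$config)) res$config$seed else NA,
    config = if (!is.null(res$config)) unclass(res$config) else NULL,
    analysis = lapply(an, function(x)
      if (is.data.frame(x)) as.list(x) else x))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(out_dir)
}

#' Sense/antisense scatter of a per-gene expression table
#'
#' Quick-look QC plot: vegetative antisense average against sense
#' average, with the group-selection thresholds drawn; genes in the
#' high-antisense / low-sense rectangle are highlighted.
#'
#' @param tbl per-sample expression table ([gse_sample()]).
#' @param cfg an [analysis_config()] supplying the thresholds.
#' @param ... passed to [plot()].
#' @export
plot_sense_antisense <- function(tbl, cfg = analysis_config(), ...) {
  sel <- tbl$gene_id %in% select_high_antisense_low_sense(tbl, cfg)
  graphics::plot(tbl$sense_avg, tbl$antisense_avg,
                 col = ifelse(sel, "red", "grey40"), pch = 16, cex = 0.6,
                 xlab = "sense average (log2)",
                 ylab = "antisense average (log2)", ...)
  graphics::abline(v = cfg$sense_max, h = cfg$antisense_min, lty = 2)
  invisible(sel)
}
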