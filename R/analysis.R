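#' Analysis thresholds for gene-level comparisons
#'
#' Houses the printed cutoffs of the study design: the high-antisense /
#' low-sense group is sense < 1 and antisense > 0.5 (log2 normalized
#' units, strict inequalities); antisense segments are called above 1.0;
#' differential sense expression uses a log2 difference > 1; newly
#' appearing antisense RNAs use a ratio of stored intensity values
#' (6 h / veg) > 2. Vegetative antisense values at or below 0 (possible
#' on the background-anchored log scale) are floored at
#' `antisense_floor` before the ratio is taken.
#'
#' @param sense_max,antisense_min group-selection cutoffs.
#' @param antisense_call_threshold segment-level antisense calling cutoff.
#' @param differential_delta log2 sense difference cutoff.
#' @param new_antisense_ratio ratio cutoff on stored intensity values.
#' @param antisense_floor positive floor applied to the ratio denominator.
#' @param bh_correct apply Benjamini-Hochberg across enrichment tests
#'   (off by default; single enrichment p-values are reported raw).
#' @export
analysis_config <- function(sense_max = 1, antisense_min = 0.5,
                            antisense_call_threshold = 1.0,
                            differential_delta = 1,
                            new_antisense_ratio = 2,
                            antisense_floor = 0.05,
                            bh_correct = FALSE) {
  cfg <- list(sense_max = sense_max, antisense_min = antisense_min,
              antisense_call_threshold = antisense_call_threshold,
              differential_delta = differential_delta,
              new_antisense_ratio = new_antisense_ratio,
              antisense_floor = antisense_floor, bh_correct = bh_correct)
  stopifnot(all(vapply(cfg[1:6], is.finite, logical(1))),
            antisense_floor > 0)
  structure(cfg, class = "analysis_config")
}

#' Select genes with high antisense and low sense expression
#'
#' The vegetative-repression signature: genes whose sense average is
#' strictly below `sense_max` and antisense average strictly above
#' `antisense_min`. Genes missing either value are excluded.
#'
#' @param tbl per-sample expression (`gene_id`, `sense_avg`,
#'   `antisense_avg`; see [gse_sample()]).
#' @param cfg an [analysis_config()].
#' @return character vector of gene ids.
#' @export
select_high_antisense_low_sense <- function(tbl, cfg = analysis_config()) {
  ok <- !is.na(tbl$sense_avg) & !is.na(tbl$antisense_avg) &
    tbl$sense_avg < cfg$sense_max & tbl$antisense_avg > cfg$antisense_min
  tbl$gene_id[ok]
}

#' Genes with increased sense expression between two samples
#'
#' @param tblA,tblB per-sample expression tables (same universe; computed
#'   on the intersection with a warning otherwise).
#' @param delta log2 difference cutoff (strict).
#' @return character vector of gene ids with
#'   `sense_avg(A) - sense_avg(B) > delta`.
#' @export
differential_sense <- function(tblA, tblB, delta = 1) {
  common <- intersect(tblA$gene_id, tblB$gene_id)
  if (length(common) < length(union(tblA$gene_id, tblB$gene_id)))
    warning("gene universes differ; using the intersection of ",
            length(common), " genes")
  a <- tblA$sense_avg[match(common, tblA$gene_id)]
  b <- tblB$sense_avg[match(common, tblB$gene_id)]
  ok <- !is.na(a) & !is.na(b) & (a - b > delta)
  common[ok]
}

#' Genes whose antisense RNA newly appears between two samples
#'
#' Selects genes with `antisense_avg(t1) / antisense_avg(t0) >` the
#' configured ratio, on the stored (log2-normalized) intensity values;
#' denominators at or below the floor are raised to it. Genes already
#' annotated in `exclude` (e.g. meiotic genes, when asking for antisense
#' over non-meiotic genes) can be removed before the cutoff.
#'
#' @param tbl_t0,tbl_t1 expression tables at the two time points.
#' @param cfg an [analysis_config()].
#' @param exclude optional gene ids to drop before the cutoff.
#' @return character vector of gene ids.
#' @export
select_new_antisense <- function(tbl_t0, tbl_t1, cfg = analysis_config(),
                                 exclude = NULL) {
  common <- intersect(tbl_t0$gene_id, tbl_t1$gene_id)
  if (!is.null(exclude)) common <- setdiff(common, exclude)
  a0 <- tbl_t0$antisense_avg[match(common, tbl_t0$gene_id)]
  a1 <- tbl_t1$antisense_avg[match(common, tbl_t1$gene_id)]
  a0 <- pmax(a0, cfg$antisense_floor)
  ok <- !is.na(a0) & !is.na(a1) & (a1 / a0 > cfg$new_antisense_ratio)
  common[ok]
}

#' Correlation between sense and antisense expression changes
#'
#' Pearson correlation between per-gene sense deltas and antisense
#' deltas across two samples; a negative value is the signature of
#' mutual suppression of sense and antisense transcription.
#'
#' @param tbl_t0,tbl_t1 expression tables at the two time points.
#' @param genes optional gene-id subset (default: all genes with
#'   complete data).
#' @return Pearson r; `NA` with a warning when a delta has zero variance
#'   (e.g. identical tables — never silently 0).
#' @export
delta_correlation <- function(tbl_t0, tbl_t1, genes = NULL) {
  common <- intersect(tbl_t0$gene_id, tbl_t1$gene_id)
  if (!is.null(genes)) common <- intersect(common, genes)
  i0 <- match(common, tbl_t0$gene_id); i1 <- match(common, tbl_t1$gene_id)
  ds <- tbl_t1$sense_avg[i1] - tbl_t0$sense_avg[i0]
  da <- tbl_t1$antisense_avg[i1] - tbl_t0$antisense_avg[i0]
  ok <- !is.na(ds) & !is.na(da)
  if (sum(ok) < 3L) stop("fewer than 3 genes with complete paired data")
  if (stats::sd(ds[ok]) == 0 || stats::sd(da[ok]) == 0) {
    warning("zero variance in deltas; correlation undefined")
    return(NA_real_)
  }
  stats::cor(ds[ok], da[ok])
}

#' Meiotic induction status of genes
#'
#' A gene counts as induced when its sense expression increases (strictly
#' positive delta, no magnitude threshold) at either meiotic time point
#' relative to vegetative growth.
#'
#' @param tbl_veg,tbl_4h,tbl_6h expression tables.
#' @param genes gene ids to assess (default: all in `tbl_veg`).
#' @return data.frame `gene_id`, `induced` (logical; `NA` when data are
#'   missing at all time points).
#' @export
meiotic_induction_status <- function(tbl_veg, tbl_4h, tbl_6h, genes = NULL) {
  genes <- genes %||% tbl_veg$gene_id
  v <- tbl_veg$sense_avg[match(genes, tbl_veg$gene_id)]
  s4 <- tbl_4h$sense_avg[match(genes, tbl_4h$gene_id)]
  s6 <- tbl_6h$sense_avg[match(genes, tbl_6h$gene_id)]
  d4 <- s4 - v; d6 <- s6 - v
  induced <- (d4 > 0) | (d6 > 0)
  induced[is.na(d4) & is.na(d6)] <- NA
  induced[is.na(induced) & ((!is.na(d4) & d4 > 0) | (!is.na(d6) & d6 > 0))] <- TRUE
  data.frame(gene_id = genes, induced = induced, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test for over-representation of an annotated
#' gene set within a selection, P(X >= k) with k the annotated genes in
#' the selection, computed in log space for tail stability.
#'
#' @param selection selected gene ids.
#' @param annotated annotated gene ids (e.g. a functional category);
#'   must lie within `universe`.
#' @param universe background gene ids.
#' @return data.frame `k`, `n`, `K`, `N`, `p_value`.
#' @export
hypergeometric_enrichment <- function(selection, annotated, universe) {
  if (length(universe) == 0L) stop("empty universe")
  selection <- intersect(selection, universe)
  annotated <- intersect(annotated, universe)
  k <- length(intersect(selection, annotated))
  n <- length(selection); K <- length(annotated); N <- length(universe)
  logp <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  data.frame(k = k, n = n, K = K, N = N, p_value = exp(logp))
}
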