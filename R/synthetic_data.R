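#' Simulation configuration
#'
#' Parameters of the synthetic tiling-array study: a random genome carrying
#' planted transcript architectures, a two-strand 25-nt tiling probe design,
#' multiplicative lognormal probe affinities, a genomic-DNA reference
#' channel, and per-condition abundance programs. The planted architectures
#' mirror the transcript classes seen around vegetatively repressed meiotic
#' genes: covering antisense RNAs that are either discrete units or multi-kb
#' 3'UTR extensions of a convergent neighbor, meiotic induction with
#' antisense decrease, derepression of a gene subset in a forkhead-deletion
#' background, internal bidirectional promoters (ACGCTC hexamer) emitting a
#' truncated sense plus a divergent antisense RNA, forkhead motifs
#' (GTAAAYA) at meiotic promoters, and intron-containing genes in spliced
#' or unspliced states.
#'
#' Abundances are linear units on the scale of the background level
#' (default 1), so a transcript of abundance `A` lands at
#' `log2(1 + A/background_level)` after gDNA normalization; the defaults
#' put expressed sense mRNAs near 3 and background antisense near 0.3 on
#' the log2 scale, keeping the 0.5 / 1.0 analysis thresholds meaningful.
#'
#' @param seed integer; fully determines all generator output.
#' @param genome_length chromosome length in nt.
#' @param n_genes total number of annotated genes (a 3'UTR-extension
#'   architecture consumes two of them: the meiotic gene and its convergent
#'   neighbor).
#' @param probe_step tiling pitch in nt (25 = end-to-end 25-mers).
#' @param affinity_sigma sdlog of the lognormal per-probe affinities
#'   (drawn with mean 1).
#' @param background_level background abundance added inside the
#'   affinity-scaled term, shared by RNA and gDNA channels.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (lognormal, mean-1) measurement noise.
#' @param gdna_level copy level of the genomic-DNA channel.
#' @param conditions RNA sample conditions, subset of
#'   `c("veg","mei4h","mei6h","fkh2")`.
#' @param arch named integer list of planted architecture counts:
#'   `mid_meiotic_discrete`, `mid_meiotic_utr3`, `fkh2_responsive` (subset
#'   of the mid-meiotic genes), `internal_bidirectional`, `new_antisense`,
#'   `fold_change`, `correlated_change`, `spliced`, `unspliced`.
#' @param motif_fraction fraction of meiotically induced antisense starts
#'   that get a forkhead motif planted within 200 nt upstream.
#' @param delta_sd,delta_rho standard deviation and correlation of the
#'   bivariate log2 (sense, antisense) change planted in the
#'   `correlated_change` gene class between veg and 6 h.
#' @param levels optional list overriding the per-class abundance programs
#'   (see the package vignette for the defaults and their rationale).
#' @param structure_seed optional; when set, genome/annotation/truth are
#'   drawn from this seed while intensities use `seed`, so changing only
#'   `seed` re-draws noise on a fixed structure.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_genes = 30L,
                       probe_step = 25L,
                       affinity_sigma = 0.5,
                       background_level = 1,
                       noise_cv = 0.25,
                       gdna_level = 20,
                       conditions = c("veg", "mei4h", "mei6h", "fkh2"),
                       arch = list(),
                       motif_fraction = 0.8,
                       delta_sd = 1,
                       delta_rho = -0.4,
                       levels = list(),
                       structure_seed = NULL) {
  arch_def <- list(mid_meiotic_discrete = 4L, mid_meiotic_utr3 = 4L,
                   fkh2_responsive = 5L, internal_bidirectional = 3L,
                   new_antisense = 4L, fold_change = 3L,
                   correlated_change = 0L, spliced = 3L, unspliced = 2L)
  arch_def[names(arch)] <- arch
  lev_def <- list(
    normal_sense = 8, background_antisense = 0.2,
    mid_sense = c(veg = 0.1, mei4h = 3, mei6h = 8),
    mid_anti = c(veg = 3, mei4h = 1.2, mei6h = 0.7),
    fkh2_derepressed_sense = 3,
    utr3_extension = c(veg = 5, mei4h = 2, mei6h = 1),
    new_sense = c(veg = 8, mei4h = 6, mei6h = 3.5),
    new_anti = c(veg = 0.15, mei4h = 1, mei6h = 3),
    trunc_sense = 4, div_anti = 2.5,
    internal_meiotic_sense = c(veg = 0.05, mei4h = 3, mei6h = 8),
    fold_change_sense = c(veg = 24, mei4h = 48, mei6h = 48),
    corr_base = 10,
    jitter_sd_normal = 0.4, jitter_sd_other = 0.2
  )
  lev_def[names(levels)] <- levels
  if (!all(conditions %in% c("veg", "mei4h", "mei6h", "fkh2")))
    stop("conditions must be a subset of veg, mei4h, mei6h, fkh2")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), probe_step = as.integer(probe_step),
              affinity_sigma = affinity_sigma, background_level = background_level,
              noise_cv = noise_cv, gdna_level = gdna_level,
              conditions = conditions, arch = arch_def,
              motif_fraction = motif_fraction,
              delta_sd = delta_sd, delta_rho = delta_rho,
              levels = lev_def, structure_seed = structure_seed)
  stopifnot(cfg$genome_length > 0, cfg$probe_step >= 1L,
            cfg$affinity_sigma >= 0, cfg$background_level >= 0,
            cfg$noise_cv >= 0, cfg$gdna_level > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Expected normalized level for a planted abundance
#'
#' Under the multiplicative simulator and gDNA normalization, a transcript
#' of linear abundance `A` over background `bg` is expected at
#' `log2(1 + A/bg)` on the normalized log2 scale.
#' @param A linear abundance.
#' @param background background level.
#' @export
expected_log2_level <- function(A, background = 1) log2(1 + A / background)

cond_level <- function(spec_levels, conds) {
  # expand a scalar or named per-condition vector to all conditions;
  # fkh2 follows veg unless stated
  out <- stats::setNames(numeric(length(conds)), conds)
  if (length(spec_levels) == 1L && is.null(names(spec_levels))) {
    out[] <- spec_levels
  } else {
    base <- if ("veg" %in% names(spec_levels)) spec_levels[["veg"]] else spec_levels[[1L]]
    out[] <- base
    for (cn in intersect(names(spec_levels), conds)) out[cn] <- spec_levels[[cn]]
    if ("fkh2" %in% conds && !("fkh2" %in% names(spec_levels)))
      out["fkh2"] <- base
  }
  out
}

#' Generate a synthetic genome, annotation, and transcript truth
#'
#' Places genes left to right on one chromosome with randomized intergenic
#' gaps, assigns each gene one of the planted architecture classes, writes
#' the corresponding forkhead (GTAAAYA) and internal-promoter (ACGCTC)
#' motifs into the sequence, and records every planted transcript with its
#' per-condition abundance program in a truth table.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `genes`, `exons`
#'   (annotation tables, see [gene_models()]; `genes` carries extra
#'   generator columns `class` and `fkh2_responsive`), `truth`
#'   (transcript table with `ab_<condition>` abundance columns), and
#'   `features` (planted motif positions).
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$structure_seed %||% config$seed)
  conds <- config$conditions
  lev <- config$levels
  chrom <- "chrI"
  L <- config$genome_length
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  empty <- function() {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), cds_start = integer(),
                        cds_end = integer(), utr3_end = integer(),
                        class = character(), fkh2_responsive = logical(),
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(), start = integer(), end = integer())
    truth <- data.frame(transcript_id = character(), chrom = character(),
                        strand = character(), start = integer(), end = integer(),
                        class = character(), spliced = logical(),
                        parent_gene = character(), covering = logical(),
                        stringsAsFactors = FALSE)
    for (cn in conds) truth[[paste0("ab_", cn)]] <- numeric()
    features <- data.frame(feature = character(), chrom = character(),
                           strand = character(), start = integer(),
                           end = integer(), gene_id = character(),
                           stringsAsFactors = FALSE)
    planted <- data.frame(gene_id = character(), delta_sense = numeric(),
                          delta_antisense = numeric(), stringsAsFactors = FALSE)
    list(genes = genes, exons = exons, truth = truth, features = features,
         planted_delta = planted)
  }
  acc <- empty()
  add_gene <- function(gene_id, strand, cds_start, cds_end, class, fkh2_resp = FALSE) {
    acc$genes[nrow(acc$genes) + 1L, ] <<-
      list(gene_id, chrom, strand, as.integer(cds_start), as.integer(cds_end),
           NA_integer_, class, fkh2_resp)
  }
  add_tx <- function(id, strand, start, end, class, ab, spliced = FALSE,
                     parent = NA_character_, covering = FALSE) {
    row <- c(list(id, chrom, strand, as.integer(max(1L, start)),
                  as.integer(min(L, end)), class, spliced, parent, covering),
             as.list(unname(ab[conds])))
    acc$truth[nrow(acc$truth) + 1L, ] <<- row
  }
  add_exons <- function(gene_id, starts, ends) {
    acc$exons <<- rbind(acc$exons,
                        data.frame(gene_id = gene_id, start = as.integer(starts),
                                   end = as.integer(ends)))
  }
  add_feature <- function(feature, strand, start, end, gene_id) {
    acc$features[nrow(acc$features) + 1L, ] <<-
      list(feature, chrom, strand, as.integer(start), as.integer(end), gene_id)
  }
  plant <- function(pos, pattern, strand = "+") {
    # overwrite genome letters with a motif (reverse-complemented on -)
    p <- strsplit(pattern, "")[[1L]]
    if (strand == "-") p <- rev(c(A = "T", C = "G", G = "C", T = "A")[p])
    idx <- pos:(pos + length(p) - 1L)
    if (idx[1L] >= 1L && idx[length(idx)] <= L) seqv[idx] <<- p
    invisible(NULL)
  }
  plant_forkhead <- function(tss, upstream_strand, gene_id) {
    # GTAAAYA within 200 nt upstream of a transcript 5' start
    off <- round(stats::runif(1, 30, 193))
    pos <- if (upstream_strand == "+") tss - off - 6L else tss + off
    motif <- sample(c("GTAAACA", "GTAAATA"), 1L)
    plant(pos, motif, upstream_strand)
    add_feature("forkhead_motif", upstream_strand, pos, pos + 6L, gene_id)
  }

  if (config$n_genes == 0L) {
    out <- empty()
    out$genome <- Biostrings::DNAStringSet(stats::setNames(paste(seqv, collapse = ""), chrom))
    return(out[c("genome", "genes", "exons", "truth", "features",
                 "planted_delta")])
  }

  a <- config$arch
  n_paired <- a$mid_meiotic_utr3
  n_special <- a$mid_meiotic_discrete + 2L * n_paired + a$internal_bidirectional +
    a$new_antisense + a$fold_change + a$correlated_change
  if (config$n_genes < n_special)
    stop("n_genes (", config$n_genes, ") is smaller than the ",
         n_special, " genes required by the architecture counts")
  n_normal <- config$n_genes - n_special

  units <- c(rep("mid_meiotic_discrete", a$mid_meiotic_discrete),
             rep("mid_meiotic_utr3", n_paired),
             rep("internal_bidirectional", a$internal_bidirectional),
             rep("new_antisense", a$new_antisense),
             rep("fold_change", a$fold_change),
             rep("correlated_change", a$correlated_change),
             rep("normal", n_normal))
  units <- sample(units)
  # which mid-meiotic genes respond to loss of the vegetative forkhead repressor
  n_mid <- a$mid_meiotic_discrete + n_paired
  fkh2_resp_idx <- if (n_mid > 0L)
    sample(n_mid, min(a$fkh2_responsive, n_mid)) else integer()
  # which normal genes carry introns, and whether they are spliced
  intron_states <- rep("none", n_normal)
  n_intr <- min(a$spliced + a$unspliced, n_normal)
  if (n_intr > 0L)
    intron_states[sample(n_normal, n_intr)] <-
      sample(c(rep("spliced", a$spliced), rep("unspliced", a$unspliced)))[seq_len(n_intr)]

  jit <- function(sd) stats::rlnorm(1L, 0, sd)
  pos <- 0L
  gi <- 0L; mid_i <- 0L; norm_i <- 0L
  motif_planned <- stats::runif(length(units)) < config$motif_fraction

  for (u in seq_along(units)) {
    kind <- units[u]
    gap <- round(stats::runif(1, 600, 1000))
    cds_len <- round(stats::runif(1, 900, 2100))
    u5 <- 60L
    u3 <- round(stats::runif(1, 60, 150))
    pos <- pos + gap
    gi <- gi + 1L
    gid <- sprintf("g%03d", gi)

    if (kind == "normal") {
      norm_i <- norm_i + 1L
      s <- sample(c("+", "-"), 1L)
      cs <- pos + 1L; ce <- cs + cds_len - 1L
      j <- jit(lev$jitter_sd_normal)
      ab_s <- cond_level(lev$normal_sense * j, conds)
      ab_a <- cond_level(lev$background_antisense * jit(0.3), conds)
      state <- intron_states[norm_i]
      add_gene(gid, s, cs, ce, if (state == "none") "normal" else state)
      tx_s <- if (s == "+") c(cs - u5, ce + u3) else c(cs - u3, ce + u5)
      if (state == "none") {
        add_exons(gid, cs, ce)
        add_tx(paste0(gid, ".t1"), s, tx_s[1L], tx_s[2L], "sense_mRNA", ab_s)
      } else {
        n_int <- sample(1:2, 1L)
        # introns placed in the CDS interior, >=150 nt from either edge
        ib <- sort(round(stats::runif(n_int, cs + 150, ce - 400)))
        ilen <- round(stats::runif(n_int, 100, 250))
        if (n_int == 2L && ib[2L] - ib[1L] < ilen[1L] + 150L) {
          n_int <- 1L; ib <- ib[1L]; ilen <- ilen[1L]
        }
        istarts <- ib; iends <- pmin(ib + ilen - 1L, ce - 150L)
        ex_st <- c(cs, iends + 1L); ex_en <- c(istarts - 1L, ce)
        keep <- ex_st <= ex_en
        add_exons(gid, ex_st[keep], ex_en[keep])
        if (state == "spliced") {
          # exonic pieces only: intron probes see no sense signal
          pieces_st <- ex_st[keep]; pieces_en <- ex_en[keep]
          pieces_st[1L] <- tx_s[1L]; pieces_en[length(pieces_en)] <- tx_s[2L]
          for (pi in seq_along(pieces_st))
            add_tx(sprintf("%s.t%d", gid, pi), s, pieces_st[pi], pieces_en[pi],
                   "sense_mRNA", ab_s, spliced = TRUE)
        } else {
          add_tx(paste0(gid, ".t1"), s, tx_s[1L], tx_s[2L], "sense_mRNA", ab_s,
                 spliced = FALSE)
        }
      }
      add_tx(paste0(gid, ".a1"), setdiff(c("+", "-"), s), cs - 50L, ce + 50L,
             "noncoding", ab_a, parent = gid)
      pos <- ce + u3 + u5
    } else if (kind == "mid_meiotic_discrete" || kind == "new_antisense") {
      s <- sample(c("+", "-"), 1L)
      as_ <- setdiff(c("+", "-"), s)
      cs <- pos + 1L; ce <- cs + cds_len - 1L
      j <- jit(lev$jitter_sd_other)
      is_mid <- kind == "mid_meiotic_discrete"
      if (is_mid) {
        mid_i <- mid_i + 1L
        resp <- mid_i %in% fkh2_resp_idx
        ab_s <- cond_level(lev$mid_sense, conds) * j
        if ("fkh2" %in% conds && resp) ab_s["fkh2"] <- lev$fkh2_derepressed_sense * j
        ab_a <- cond_level(lev$mid_anti, conds) * jit(lev$jitter_sd_other)
      } else {
        resp <- FALSE
        ab_s <- cond_level(lev$new_sense, conds) * j
        ab_a <- cond_level(lev$new_anti, conds) * jit(lev$jitter_sd_other)
      }
      add_gene(gid, s, cs, ce, kind, resp)
      add_exons(gid, cs, ce)
      tx_s <- if (s == "+") c(cs - u5, ce + u3) else c(cs - u3, ce + u5)
      add_tx(paste0(gid, ".t1"), s, tx_s[1L], tx_s[2L], "sense_mRNA", ab_s)
      a5 <- round(stats::runif(1, 150, 350)); a3 <- round(stats::runif(1, 150, 350))
      at <- c(cs - ifelse(as_ == "+", a5, a3), ce + ifelse(as_ == "+", a3, a5))
      add_tx(paste0(gid, ".a1"), as_, at[1L], at[2L], "antisense_discrete",
             ab_a, parent = gid, covering = TRUE)
      tss <- if (s == "+") tx_s[1L] else tx_s[2L]
      if (is_mid) plant_forkhead(tss, s, gid)
      if (!is_mid && motif_planned[u]) {
        as_tss <- if (as_ == "+") at[1L] else at[2L]
        plant_forkhead(as_tss, as_, gid)
      }
      pos <- max(ce + u3 + u5, at[2L])
    } else if (kind == "mid_meiotic_utr3") {
      mid_i <- mid_i + 1L
      resp <- mid_i %in% fkh2_resp_idx
      flip <- sample(c(TRUE, FALSE), 1L)
      n_len <- round(stats::runif(1, 900, 1800))
      g_nm <- round(stats::runif(1, 120, 250))
      ext3 <- round(stats::runif(1, 60, 150))
      nid <- gid
      gi <- gi + 1L
      mid_id <- sprintf("g%03d", gi)
      jn <- jit(lev$jitter_sd_other); jm <- jit(lev$jitter_sd_other)
      ab_ext <- cond_level(lev$utr3_extension, conds) * jn
      ab_m <- cond_level(lev$mid_sense, conds) * jm
      if ("fkh2" %in% conds && resp) ab_m["fkh2"] <- lev$fkh2_derepressed_sense * jm
      ab_bgN <- cond_level(lev$background_antisense * jit(0.3), conds)
      if (!flip) {
        # neighbor N (+) ... convergent meiotic gene M (-): N's transcript
        # runs through its long 3'UTR across all of M
        ns <- pos + 1L; ne <- ns + n_len - 1L
        ms <- ne + g_nm; me <- ms + cds_len - 1L
        add_gene(nid, "+", ns, ne, "utr3_neighbor")
        add_gene(mid_id, "-", ms, me, "mid_meiotic_utr3", resp)
        add_exons(nid, ns, ne); add_exons(mid_id, ms, me)
        add_tx(paste0(nid, ".t1"), "+", ns - u5, me + ext3,
               "antisense_utr3_extension", ab_ext, parent = mid_id,
               covering = TRUE)
        add_tx(paste0(mid_id, ".t1"), "-", ms - u3, me + u5, "sense_mRNA", ab_m)
        add_tx(paste0(nid, ".a1"), "-", ns, ne, "noncoding", ab_bgN, parent = nid)
        plant_forkhead(me + u5, "-", mid_id)
        acc$genes$utr3_end[acc$genes$gene_id == nid] <- as.integer(me + ext3)
        pos <- me + ext3
      } else {
        # mirrored: meiotic gene M (+) ... neighbor N (-) extending leftwards
        ms <- pos + 1L; me <- ms + cds_len - 1L
        ns <- me + g_nm; ne <- ns + n_len - 1L
        add_gene(nid, "-", ns, ne, "utr3_neighbor")
        add_gene(mid_id, "+", ms, me, "mid_meiotic_utr3", resp)
        add_exons(nid, ns, ne); add_exons(mid_id, ms, me)
        add_tx(paste0(nid, ".t1"), "-", ms - ext3, ne + u5,
               "antisense_utr3_extension", ab_ext, parent = mid_id,
               covering = TRUE)
        add_tx(paste0(mid_id, ".t1"), "+", ms - u5, me + u3, "sense_mRNA", ab_m)
        add_tx(paste0(nid, ".a1"), "+", ns, ne, "noncoding", ab_bgN, parent = nid)
        plant_forkhead(ms - u5, "+", mid_id)
        acc$genes$utr3_end[acc$genes$gene_id == nid] <- as.integer(ms - ext3)
        pos <- ne + u5
      }
    } else if (kind == "internal_bidirectional") {
      s <- sample(c("+", "-"), 1L)
      as_ <- setdiff(c("+", "-"), s)
      cs <- pos + 1L; ce <- cs + cds_len - 1L
      j <- jit(lev$jitter_sd_other)
      ab_tr <- cond_level(lev$trunc_sense * j, conds)
      ab_da <- cond_level(lev$div_anti * jit(lev$jitter_sd_other), conds)
      ab_full <- cond_level(lev$internal_meiotic_sense, conds) * j
      if (any(c("mei4h", "mei6h") %in% conds)) {
        # in meiosis the full-length promoter takes over
        ab_tr[intersect(c("mei4h", "mei6h"), conds)] <- 0.2
        ab_da[intersect(c("mei4h", "mei6h"), conds)] <- 0.2
      }
      add_gene(gid, s, cs, ce, kind)
      add_exons(gid, cs, ce)
      div_ext <- round(stats::runif(1, 200, 350))
      if (s == "+") {
        p <- cs + round(0.6 * cds_len)
        add_tx(paste0(gid, ".t1"), "+", p, ce + u3, "truncated_sense", ab_tr,
               parent = gid)
        add_tx(paste0(gid, ".a1"), "-", cs - div_ext, p - 1L,
               "divergent_internal_antisense", ab_da, parent = gid)
        add_tx(paste0(gid, ".t2"), "+", cs - u5, ce + u3, "sense_mRNA", ab_full)
        plant(p, "ACGCTC", "+")
        add_feature("internal_hexamer", "+", p, p + 5L, gid)
        plant_forkhead(cs - u5, "+", gid)
      } else {
        p <- cs + round(0.4 * cds_len)
        add_tx(paste0(gid, ".t1"), "-", cs - u3, p, "truncated_sense", ab_tr,
               parent = gid)
        add_tx(paste0(gid, ".a1"), "+", p + 1L, ce + div_ext,
               "divergent_internal_antisense", ab_da, parent = gid)
        add_tx(paste0(gid, ".t2"), "-", cs - u3, ce + u5, "sense_mRNA", ab_full)
        plant(p, "ACGCTC", "+")
        add_feature("internal_hexamer", "+", p, p + 5L, gid)
        plant_forkhead(ce + u5, "-", gid)
      }
      pos <- ce + max(u3 + u5, div_ext)
    } else if (kind == "fold_change") {
      s <- sample(c("+", "-"), 1L)
      cs <- pos + 1L; ce <- cs + cds_len - 1L
      j <- jit(lev$jitter_sd_other)
      ab_s <- cond_level(lev$fold_change_sense, conds) * j
      ab_a <- cond_level(lev$background_antisense * jit(0.3), conds)
      add_gene(gid, s, cs, ce, "fold_change")
      add_exons(gid, cs, ce)
      tx_s <- if (s == "+") c(cs - u5, ce + u3) else c(cs - u3, ce + u5)
      add_tx(paste0(gid, ".t1"), s, tx_s[1L], tx_s[2L], "sense_mRNA", ab_s)
      add_tx(paste0(gid, ".a1"), setdiff(c("+", "-"), s), cs - 50L, ce + 50L,
             "noncoding", ab_a, parent = gid)
      pos <- ce + u3 + u5
    } else if (kind == "correlated_change") {
      s <- sample(c("+", "-"), 1L)
      as_ <- setdiff(c("+", "-"), s)
      cs <- pos + 1L; ce <- cs + cds_len - 1L
      j <- jit(lev$jitter_sd_other)
      # bivariate normal log2 change between veg and 6 h
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      ds <- config$delta_sd * z1
      da <- config$delta_sd * (config$delta_rho * z1 +
                                 sqrt(1 - config$delta_rho^2) * z2)
      base <- lev$corr_base * j
      ab_s <- cond_level(base, conds)
      ab_a <- cond_level(base, conds)
      if ("mei6h" %in% conds) {
        ab_s["mei6h"] <- base * 2^ds
        ab_a["mei6h"] <- base * 2^da
      }
      add_gene(gid, s, cs, ce, "correlated_change")
      add_exons(gid, cs, ce)
      tx_s <- if (s == "+") c(cs - u5, ce + u3) else c(cs - u3, ce + u5)
      add_tx(paste0(gid, ".t1"), s, tx_s[1L], tx_s[2L], "sense_mRNA", ab_s)
      a5 <- round(stats::runif(1, 100, 250))
      add_tx(paste0(gid, ".a1"), as_, cs - a5, ce + a5, "antisense_discrete",
             ab_a, parent = gid, covering = TRUE)
      acc$planted_delta[nrow(acc$planted_delta) + 1L, ] <- list(gid, ds, da)
      pos <- ce + u3 + a5
    }
    if (pos > L - 200L)
      stop("genome_length (", L, ") too short for ", config$n_genes,
           " genes: ran out of sequence at unit ", u,
           "; increase genome_length or reduce n_genes")
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(paste(seqv, collapse = ""), chrom))
  genes <- gene_models(acc$genes, acc$exons)
  list(genome = genome, genes = genes, exons = acc$exons,
       truth = acc$truth, features = acc$features,
       planted_delta = acc$planted_delta)
}

#' Design end-to-end tiling probes on both strands
#'
#' Emits 25-nt probes starting every `step` nt on both strands of every
#' chromosome; per chromosome the count is `2 * (floor((L-25)/step) + 1)`.
#'
#' @param genome a `DNAStringSet`.
#' @param step tiling pitch in nt (>= 1).
#' @return data.frame `probe_id`, `sequence`, `chrom`, `strand`, `start`.
#' @export
design_tiling_probes <- function(genome, step = 25L) {
  stopifnot(step >= 1L)
  out <- list()
  for (chrom in names(genome)) {
    Lc <- Biostrings::width(genome[chrom])
    if (Lc < PROBE_LEN) {
      warning("chromosome ", chrom, " shorter than 25 nt: no probes designed")
      next
    }
    starts <- seq.int(1L, Lc - PROBE_LEN + 1L, by = step)
    fwd <- Biostrings::extractAt(genome[[chrom]],
                                 IRanges::IRanges(starts, width = PROBE_LEN))
    out[[length(out) + 1L]] <- data.frame(
      probe_id = sprintf("%s_p_%07d", chrom, starts),
      sequence = as.character(fwd),
      chrom = chrom, strand = "+", start = starts, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      probe_id = sprintf("%s_m_%07d", chrom, starts),
      sequence = as.character(Biostrings::reverseComplement(fwd)),
      chrom = chrom, strand = "-", start = starts, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(probe_id = character(), sequence = character(),
                      chrom = character(), strand = character(),
                      start = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate raw probe intensities (RNA conditions + gDNA channel)
#'
#' Each probe i gets a lognormal affinity `a_i` (mean 1, sdlog
#' `affinity_sigma`). For an RNA condition, the raw value is
#' `a_i * (A_i + bg) * noise` where `A_i` sums the abundances of truth
#' transcripts on the probe's strand overlapping its footprint by >= 1 nt,
#' `bg` is the background level and `noise` is lognormal with mean 1 and
#' CV `noise_cv`. The gDNA channel is `a_i * (G + bg) * noise` with `G`
#' the constant genomic copy level. The background sits inside the
#' affinity-scaled term, the regime in which ratio-to-gDNA normalization
#' removes probe effects exactly; with zero planted abundance the expected
#' raw value is exactly `bg`.
#'
#' @param truth transcript truth table from
#'   [generate_genome_and_annotation()].
#' @param probes probe map (or tiling design with coordinates).
#' @param config a [sim_config()].
#' @return an [intensity_matrix()] with one column per RNA condition plus
#'   a `gdna` column.
#' @export
simulate_intensities <- function(truth, probes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 500009L)
  conds <- config$conditions
  n <- nrow(probes)
  sigma <- config$affinity_sigma
  aff <- stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
  sl <- sqrt(log(1 + config$noise_cv^2))
  noise <- function() stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
  bg <- config$background_level

  A <- matrix(0, nrow = n, ncol = length(conds),
              dimnames = list(NULL, conds))
  if (nrow(truth) > 0L) {
    tgr <- GenomicRanges::GRanges(truth$chrom,
                                  IRanges::IRanges(truth$start, truth$end),
                                  strand = truth$strand)
    ov <- GenomicRanges::findOverlaps(probes_gr(probes), tgr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (cn in conds) {
        s <- rowsum(truth[[paste0("ab_", cn)]][sh], group = qh)
        A[as.integer(rownames(s)), cn] <- s[, 1L]
      }
    }
  }
  A[is.na(A)] <- 0
  values <- matrix(0, nrow = n, ncol = length(conds) + 1L,
                   dimnames = list(probes$probe_id, c(conds, "gdna")))
  for (cn in conds) values[, cn] <- aff * (A[, cn] + bg) * noise()
  values[, "gdna"] <- aff * (config$gdna_level + bg) * noise()
  samples <- data.frame(sample = c(conds, "gdna"),
                        condition = c(conds, "gdna"),
                        channel = c(rep("RNA", length(conds)), "gDNA"),
                        stringsAsFactors = FALSE)
  im <- intensity_matrix(values, samples)
  attr(im, "affinity") <- stats::setNames(aff, probes$probe_id)
  im
}
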