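#' Change-point segmentation model parameters
#'
#' The per-strand probe signal is modelled as piecewise constant with
#' Gaussian residuals. For each candidate number of segments k the optimal
#' boundaries minimize the residual sum of squares (exact dynamic
#' programming over prefix sums); k is then chosen to maximize the
#' penalized Gaussian log-likelihood
#' `-(n/2) * log(RSS_k / n) - (penalty/2) * k * log(n)`
#' (`penalty = 2` is the BIC rate). Among equal-RSS segmentations the one
#' with fewer segments, then leftmost boundaries, is preferred.
#'
#' Exact DP is quadratic in the number of probes, so chromosomes longer
#' than `chunk_size` probes are processed in overlapping chunks whose
#' boundaries are reconciled in the overlap; results carry an `exact`
#' flag saying whether chunking was needed.
#'
#' @param max_segments maximum segments per chunk (S).
#' @param penalty penalty rate lambda (2 = BIC).
#' @param min_probes minimum probes per segment (~100 nt at 25-nt pitch
#'   with the default 4), suppressing single-probe artifacts.
#' @param chunk_size,chunk_overlap chunking parameters in probes.
#' @return a `segmentation_model` list.
#' @export
segmentation_model <- function(max_segments = 100L, penalty = 2,
                               min_probes = 4L, chunk_size = 3000L,
                               chunk_overlap = 300L) {
  stopifnot(max_segments >= 1L, min_probes >= 1L,
            chunk_size > chunk_overlap, chunk_overlap >= 0L)
  structure(list(max_segments = as.integer(max_segments), penalty = penalty,
                 min_probes = as.integer(min_probes),
                 chunk_size = as.integer(chunk_size),
                 chunk_overlap = as.integer(chunk_overlap)),
            class = "segmentation_model")
}

#' Penalized criterion of a given segmentation
#'
#' @param values numeric signal vector.
#' @param starts 1-based segment start indices (first element 1).
#' @param penalty penalty rate lambda.
#' @return the penalized log-likelihood (larger is better).
#' @export
segmentation_criterion <- function(values, starts, penalty = 2) {
  n <- length(values)
  ends <- c(starts[-1L] - 1L, n)
  rss <- sum(vapply(seq_along(starts), function(i) {
    seg <- values[starts[i]:ends[i]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  -n / 2 * log(max(rss, n * 1e-12) / n) - penalty / 2 * length(starts) * log(n)
}

#' Segment a signal vector into constant-mean pieces
#'
#' @param values ordered numeric vector (all finite).
#' @param model a [segmentation_model()].
#' @return list with `starts` (1-based segment start indices, first = 1),
#'   `k`, `rss` (RSS per candidate k), and `criterion` (penalized
#'   criterion per candidate k).
#' @export
segment_signal <- function(values, model = segmentation_model()) {
  n <- length(values)
  if (n < 1L) stop("empty signal")
  if (!all(is.finite(values))) stop("signal contains non-finite values")
  if (n < 2L * model$min_probes)
    return(list(starts = 1L, k = 1L, rss = sum((values - mean(values))^2),
                criterion = NA_real_))
  res <- segment_dp_cpp(values, model$max_segments, model$min_probes)
  ks <- seq_along(res$rss)
  crit <- -n / 2 * log(pmax(res$rss, n * 1e-12) / n) -
    model$penalty / 2 * ks * log(n)
  k <- which.max(crit)  # ties resolve to the smaller k
  list(starts = res$starts[[k]], k = k, rss = res$rss, criterion = crit)
}

# chunked segmentation of one long vector; returns segment start indices
segment_signal_chunked <- function(values, model) {
  n <- length(values)
  if (n <= model$chunk_size) {
    out <- segment_signal(values, model)$starts
    attr(out, "exact") <- TRUE
    return(out)
  }
  ov <- model$chunk_overlap
  step <- model$chunk_size - ov
  cps <- integer(0)  # change points: segment starts > 1
  pos <- 1L
  repeat {
    end <- min(pos + model$chunk_size - 1L, n)
    local <- segment_signal(values[pos:end], model)$starts
    local_cps <- local[-1L] + pos - 1L
    # keep change points in the chunk core; the overlap halves belong to
    # the neighboring chunks (cores partition (lo, hi] exactly)
    lo <- if (pos == 1L) 1L else pos + ov %/% 2L - 1L
    hi <- if (end == n) n else end - ov %/% 2L
    cps <- c(cps, local_cps[local_cps > lo & local_cps <= hi])
    if (end == n) break
    pos <- pos + step
  }
  out <- c(1L, sort(unique(cps)))
  out <- merge_short_segments(values, out, model$min_probes)
  attr(out, "exact") <- FALSE
  out
}

# enforce the min-probes invariant after chunk reconciliation by merging
# any short segment into the neighbor with the closer mean
merge_short_segments <- function(values, starts, min_probes) {
  repeat {
    n <- length(values)
    ends <- c(starts[-1L] - 1L, n)
    len <- ends - starts + 1L
    if (length(starts) == 1L || all(len >= min_probes)) return(starts)
    i <- which(len < min_probes)[1L]
    m <- vapply(seq_along(starts),
                function(j) mean(values[starts[j]:ends[j]]), numeric(1))
    drop_left <- if (i == 1L) FALSE
      else if (i == length(starts)) TRUE
      else abs(m[i] - m[i - 1L]) <= abs(m[i] - m[i + 1L])
    starts <- if (drop_left) starts[-i] else starts[-(i + 1L)]
  }
}

#' Segment normalized signal genome-wide
#'
#' Applies [segment_signal()] to the ordered unique-probe vector of every
#' (chromosome, strand), maps probe indices back to genomic coordinates,
#' and computes segment means. Segments tile each probe vector exactly.
#'
#' @param signal a `normalized_signal` from [normalize_to_gdna()].
#' @param model a [segmentation_model()].
#' @param sample RNA sample (column of `signal$values`) to segment.
#' @return data.frame of segments: `segment_id`, `chrom`, `strand`,
#'   `first_probe`, `last_probe` (indices into the per-(chrom, strand)
#'   probe vector), `start`, `end` (genomic footprint union, 1-based
#'   closed), `n_probes`, `mean_intensity`, plus global row indices
#'   `row_first`, `row_last` into `signal$values`.
#' @export
segment_genome <- function(signal, model = segmentation_model(),
                           sample = colnames(signal$values)[1L]) {
  stopifnot(inherits(signal, "normalized_signal"))
  if (!sample %in% colnames(signal$values))
    stop("sample ", sample, " not present in the normalized signal")
  probes <- signal$probes
  vals <- signal$values[, sample]
  out <- list()
  for (chrom in unique(probes$chrom)) {
    for (str in c("+", "-")) {
      rows <- which(probes$chrom == chrom & probes$strand == str)
      if (length(rows) == 0L) next
      rows <- rows[order(probes$start[rows])]
      v <- vals[rows]
      starts <- segment_signal_chunked(v, model)
      ends <- c(starts[-1L] - 1L, length(v))
      mseg <- vapply(seq_along(starts),
                     function(i) mean(v[starts[i]:ends[i]]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        segment_id = sprintf("%s%s%04d", chrom, ifelse(str == "+", "p", "m"),
                             seq_along(starts)),
        chrom = chrom, strand = str,
        first_probe = starts, last_probe = ends,
        start = probes$start[rows[starts]],
        end = probes$start[rows[ends]] + PROBE_LEN - 1L,
        n_probes = ends - starts + 1L,
        mean_intensity = mseg,
        row_first = rows[starts], row_last = rows[ends],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("normalized signal contains no probes")
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  attr(segs, "sample") <- sample
  segs
}

#' Write segments as BED6 (and a full-field TSV alongside)
#'
#' BED is 0-based half-open; coordinates are converted from the package's
#' 1-based closed convention. The score column is the mean intensity
#' scaled by 100 and clamped to 0..1000.
#'
#' @param segments segment table from [segment_genome()].
#' @param path output BED path; a `<path>.tsv` with all columns is also
#'   written.
#' @export
write_segments_bed <- function(segments, path) {
  score <- pmax(0, pmin(1000, round(segments$mean_intensity * 100)))
  bed <- data.frame(segments$chrom, segments$start - 1L, segments$end,
                    segments$segment_id, score, segments$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(segments, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
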