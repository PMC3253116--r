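IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Scan a genome for a degenerate (IUPAC) motif
#'
#' Reports every position where the motif matches (Y = C/T, R = A/G,
#' N = any base, and so on). Minus-strand hits are found by matching the
#' reverse complement of the pattern on the plus sequence and are
#' reported with strand `-`; for those, the motif's 5' base sits at the
#' `end` coordinate, and the `five_prime` column gives the 5' base
#' position on either strand.
#'
#' @param genome a `DNAStringSet`.
#' @param motif IUPAC pattern, e.g. `"GTAAAYA"` (the forkhead
#'   transcription-factor core binding motif).
#' @param both_strands scan the minus strand as well (default `TRUE`).
#' @return data.frame `motif`, `chrom`, `strand`, `start`, `end`
#'   (1-based closed, on plus-strand coordinates), `five_prime`.
#' @export
scan_iupac <- function(genome, motif, both_strands = TRUE) {
  letters_in <- strsplit(toupper(motif), "")[[1L]]
  bad <- setdiff(letters_in, IUPAC_LETTERS)
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  pat <- Biostrings::DNAString(toupper(motif))
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (chrom in names(genome)) {
    for (str in strands) {
      p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, genome[[chrom]], fixed = FALSE)
      if (length(m)) {
        st <- Biostrings::start(m); en <- Biostrings::end(m)
        out[[length(out) + 1L]] <- data.frame(
          motif = toupper(motif), chrom = chrom, strand = str,
          start = st, end = en,
          five_prime = if (str == "+") st else en,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), five_prime = integer()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, names(genome)), res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Fraction of antisense RNAs originating near a motif
#'
#' Flags each antisense call whose 5' origin lies within `window` nt of
#' any motif hit on the same chromosome (hit position = its 5' base,
#' either strand), and returns the near fraction. Because "close" is not
#' a sharp biological quantity, a sensitivity report over several window
#' sizes is included.
#'
#' @param calls antisense calls carrying `chrom` and `origin_pos`
#'   columns ([call_antisense()]), or any data.frame with those columns
#'   (e.g. planted truth 5' starts).
#' @param hits motif hits from [scan_iupac()].
#' @param window proximity window in nt (default 500).
#' @param sensitivity_windows windows for the sensitivity report.
#' @return list with `fraction`, `n_near`, `n_total`, `flags` (per-call
#'   logical), and `sensitivity` (data.frame window / fraction).
#' @export
antisense_near_motif <- function(calls, hits, window = 500L,
                                 sensitivity_windows = c(200L, 500L, 1000L)) {
  near_at <- function(w) {
    vapply(seq_len(nrow(calls)), function(i) {
      h <- hits$five_prime[hits$chrom == calls$chrom[i]]
      any(abs(h - calls$origin_pos[i]) <= w)
    }, logical(1))
  }
  if (nrow(calls) == 0L)
    return(list(fraction = NA_real_, n_near = 0L, n_total = 0L,
                flags = logical(), sensitivity = data.frame(
                  window = sensitivity_windows, fraction = NA_real_)))
  flags <- near_at(window)
  sens <- data.frame(window = sensitivity_windows,
                     fraction = vapply(sensitivity_windows,
                                       function(w) mean(near_at(w)), numeric(1)))
  list(fraction = mean(flags), n_near = sum(flags), n_total = length(flags),
       flags = flags, sensitivity = sens)
}

#' Exact probability that a random sequence contains a word
#'
#' P(at least one occurrence of `word` in an iid uniform DNA sequence of
#' length `L`), computed exactly by propagating the state distribution of
#' the word's prefix-matching (KMP) automaton along the sequence; word
#' self-overlap is thereby handled correctly, unlike the window
#' independence approximation `1 - (1 - 4^-k)^(L-k+1)`, which
#' overstates the probability for clustering (self-overlapping) words
#' and slightly understates it otherwise.
#'
#' @param word DNA word over A/C/G/T.
#' @param L sequence length (>= nchar(word)).
#' @return containment probability.
#' @export
kmer_contain_prob <- function(word, L) {
  wc <- strsplit(toupper(word), "")[[1L]]
  k <- length(wc)
  if (L < k) return(0)
  bases <- c("A", "C", "G", "T")
  if (!all(wc %in% bases)) stop("word must be over A/C/G/T")
  # transition[s+1, b]: longest suffix of (matched prefix s + base b)
  # that is a prefix of the word; reaching k is absorbing
  trans <- matrix(0L, nrow = k, ncol = 4L)
  for (s in 0:(k - 1L)) for (b in 1:4) {
    str <- c(wc[seq_len(s)], bases[b])
    t <- 0L
    for (l in min(k, length(str)):1) {
      if (identical(str[(length(str) - l + 1L):length(str)], wc[1:l])) {
        t <- l; break
      }
    }
    trans[s + 1L, b] <- t
  }
  p <- c(1, rep(0, k))
  for (i in seq_len(L)) {
    q <- c(rep(0, k), p[k + 1L])
    for (s in 0:(k - 1L)) {
      ps <- p[s + 1L]
      if (ps == 0) next
      for (b in 1:4) {
        t <- trans[s + 1L, b]
        q[t + 1L] <- q[t + 1L] + ps / 4
      }
    }
    p <- q
  }
  p[k + 1L]
}

#' Exhaustive common k-mer discovery across sequences
#'
#' Enumerates k-mers and counts, for each, the number of input sequences
#' containing it (exact match; optionally on either strand). The
#' significance of a k-mer found in `n` of the `m` sequences is the
#' upper-tail probability of containment in at least `n` sequences under
#' an iid uniform background (Poisson-binomial over the per-sequence
#' containment probabilities `q_i`; for a k-mer present in all
#' sequences this reduces to `prod(q_i)`).
#'
#' Two background computations are available for `q_i`: `"exact"`
#' (default) uses the automaton probability of [kmer_contain_prob()];
#' `"windows"` uses the window-independence approximation
#' `q = 1 - (1 - 4^-k)^W` with `W = L - k + 1` scanned windows
#' (`2(L - k + 1)` when both strands are scanned). At the word lengths
#' of promoter analysis (k = 6, L = 400) the two agree closely; at small
#' k the approximation's bias is measurable, so the exact form is the
#' default. Both-strand containment has no single-word automaton, so
#' `both_strands = TRUE` always uses the windows approximation.
#'
#' @param sequences character vector of DNA sequences (all length >= k).
#' @param k word length.
#' @param both_strands count a k-mer as contained when present on either
#'   strand.
#' @param min_sequences only report k-mers contained in at least this
#'   many sequences (default: all of them, the common-word question).
#' @param p_method background model for the per-sequence containment
#'   probability.
#' @return data.frame `kmer`, `k`, `n_sequences_containing`, `p_value`,
#'   sorted by p then kmer; attribute `background` records the model.
#' @export
find_common_kmer <- function(sequences, k, both_strands = FALSE,
                             min_sequences = length(sequences),
                             p_method = c("exact", "windows")) {
  p_method <- match.arg(p_method)
  if (both_strands) p_method <- "windows"
  sequences <- toupper(sequences)
  L <- nchar(sequences)
  if (any(L < k)) stop("k exceeds the shortest sequence length")
  m <- length(sequences)
  kmer_set <- function(s) {
    n <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  revcomp <- function(x) {
    vapply(x, function(s) {
      paste(rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(s, "")[[1L]]]),
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  sets <- lapply(sequences, function(s) {
    ks <- kmer_set(s)
    if (both_strands) unique(c(ks, revcomp(ks))) else ks
  })
  all_kmers <- sort(unique(unlist(sets)))
  counts <- Reduce(`+`, lapply(sets, function(s)
    as.integer(all_kmers %in% s)))
  keep <- counts >= min_sequences
  kmers <- all_kmers[keep]
  W <- (L - k + 1L) * if (both_strands) 2L else 1L
  q_windows <- 1 - (1 - 4^-k)^W
  # P(contained in >= n of the m sequences); Poisson-binomial upper tail
  # by direct convolution (m is small)
  tail_p <- function(q, n) {
    pmf <- 1
    for (qi in q) pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
    sum(pmf[(n + 1L):(m + 1L)])
  }
  pv <- vapply(seq_along(kmers), function(i) {
    q <- if (p_method == "exact") {
      vapply(unique(L), function(l) kmer_contain_prob(kmers[i], l),
             numeric(1))[match(L, unique(L))]
    } else q_windows
    tail_p(q, counts[keep][i])
  }, numeric(1))
  res <- data.frame(kmer = kmers, k = k,
                    n_sequences_containing = counts[keep],
                    p_value = pmin(1, pv),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$kmer), ]
  rownames(res) <- NULL
  attr(res, "background") <- list(
    model = if (p_method == "exact") "iid uniform, exact automaton"
      else "iid uniform, window independence",
    windows = W, q_windows = q_windows,
    both_strands = both_strands, m = m)
  res
}

#' Write motif hits as BED6
#' @param hits motif hits from [scan_iupac()].
#' @param path output BED path.
#' @export
write_motif_bed <- function(hits, path) {
  bed <- data.frame(hits$chrom, hits$start - 1L, hits$end, hits$motif,
                    0L, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
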