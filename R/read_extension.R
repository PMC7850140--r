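#' Join one SM / MS clipped-read pair by head-to-tail overlap
#'
#' Compares the first \code{n} bases of the SM read with the last \code{n}
#' bases of the MS read, starting from the largest \code{n = read_length -
#' 30} and decreasing. A comparison succeeds when the two substrings match
#' exactly after discounting up to \code{shift} bases at each end of the
#' compared window (sequencing errors concentrate at clip boundaries). The
#' join at the first (largest) succeeding \code{n > min_n} wins; inside the
#' overlap the MS read's bases are kept.
#'
#' @param sm_seq,ms_seq Full read sequences (characters) of the SM and MS
#'   clipped reads.
#' @param read_length Library read length (bp).
#' @param min_n Strict minimum overlap (default 30 bp).
#' @param shift Boundary discount in bases (default 3).
#' @return \code{NULL}, or a list with \code{n}, \code{shift_used} and
#'   \code{sequence} (length \code{nchar(ms_seq) + nchar(sm_seq) - n}).
#' @export
join_pair <- function(sm_seq, ms_seq, read_length, min_n = 30L,
                      shift = 3L) {
  if (is.na(read_length) || read_length <= min_n + 1L) return(NULL)
  la <- nchar(sm_seq); lb <- nchar(ms_seq)
  n_max <- min(read_length - min_n, la, lb)
  if (n_max <= min_n) return(NULL)
  for (n in seq.int(n_max, min_n + 1L)) {
    s <- .match_shift(sm_seq, ms_seq, n, lb, shift)
    if (!is.na(s)) {
      return(list(n = as.integer(n), shift_used = s,
                  sequence = paste0(ms_seq, substr(sm_seq, n + 1L, la))))
    }
  }
  NULL
}

# Smallest s in 0..shift such that the overlap windows, trimmed by s at
# both ends, are identical; NA when none works.
.match_shift <- function(sm_seq, ms_seq, n, lb, shift) {
  for (s in 0:shift) {
    if (n - 2L * s < 1L) break
    if (substr(sm_seq, 1L + s, n - s) ==
        substr(ms_seq, lb - n + 1L + s, lb - s)) {
      return(s)
    }
  }
  NA_integer_
}

# Fast candidate overlap lengths for a pair: a 20-mer probe from the
# interior of the SM prefix (positions 5..24 are inside the exactly-matching
# core for every admissible n and shift) is located in the MS read; each hit
# implies one candidate n. Equivalent to trying all n (property-tested).
.candidate_ns <- function(sm_seq, ms_seq, read_length, min_n = 30L) {
  la <- nchar(sm_seq); lb <- nchar(ms_seq)
  n_max <- min(read_length - min_n, la, lb)
  if (n_max <= min_n || la < 24L) return(integer(0))
  probe <- substr(sm_seq, 5L, 24L)
  hits <- .find_all_fixed(probe, ms_seq)
  if (length(hits) == 0) return(integer(0))
  ns <- lb - hits + 5L
  sort(ns[ns > min_n & ns <= n_max], decreasing = TRUE)
}

# All (overlapping) start positions of a fixed pattern in text.
.find_all_fixed <- function(pattern, text) {
  pos <- integer(0)
  from <- 1L
  nt <- nchar(text)
  repeat {
    hit <- regexpr(pattern, substr(text, from, nt), fixed = TRUE)
    if (hit == -1L) break
    p <- from + as.integer(hit) - 1L
    pos <- c(pos, p)
    from <- p + 1L
  }
  pos
}

#' Extend clipped reads within 1 kb bins
#'
#' For every SM clipped read, candidate MS partners are all MS clipped reads
#' whose breakpoints lie within \code{bin_width} (1 kb). Each SM read
#' produces at most one join: the partner giving the largest overlap
#' \code{n}, ties broken by the leftmost partner breakpoint. Hard-clipped
#' records (no clipped sequence) cannot seed extension. Input clips should
#' already be quality filtered (mapping quality >= 20, non-supplementary).
#'
#' @param clips Clip data.frame (\code{\link{extract_clips}}).
#' @param read_length Library read length (bp).
#' @param config \code{\link{caller_config}}.
#' @return data.frame of extended sequences: name
#'   (\code{"<msname>|<smname>|n=<n>"}), sequence, n, shift_used, chrom, bp
#'   (leftmost of the two clip breakpoints), ms_qname, sm_qname.
#' @export
extend_clipped_reads <- function(clips, read_length,
                                 config = caller_config()) {
  empty <- data.frame(name = character(0), sequence = character(0),
                      n = integer(0), shift_used = integer(0),
                      chrom = character(0), bp = integer(0),
                      ms_qname = character(0), sm_qname = character(0),
                      stringsAsFactors = FALSE)
  usable <- clips[nzchar(clips$clipped_seq), , drop = FALSE]
  sm <- usable[usable$side == "SM", , drop = FALSE]
  ms <- usable[usable$side == "MS", , drop = FALSE]
  if (nrow(sm) == 0 || nrow(ms) == 0) return(empty)
  rows <- list()
  for (ch in unique(sm$chrom)) {
    smc <- sm[sm$chrom == ch, , drop = FALSE]
    msc <- ms[ms$chrom == ch, , drop = FALSE]
    if (nrow(msc) == 0) next
    ord <- order(msc$bp)
    msc <- msc[ord, , drop = FALSE]
    for (i in seq_len(nrow(smc))) {
      lo <- smc$bp[i] - config$bin_width
      hi <- smc$bp[i] + config$bin_width
      j0 <- findInterval(lo - 1L, msc$bp) + 1L
      j1 <- findInterval(hi, msc$bp)
      if (j0 > j1) next
      best <- NULL
      for (j in seq.int(j0, j1)) {
        if (msc$qname[j] == smc$qname[i]) next
        jp <- .join_via_probe(smc$read_seq[i], msc$read_seq[j], read_length,
                              config$min_overlap_n, config$boundary_shift)
        if (is.null(jp)) next
        if (is.null(best) || jp$n > best$n ||
            (jp$n == best$n && msc$bp[j] < best$ms_bp)) {
          best <- c(jp, list(ms_bp = msc$bp[j], ms_qname = msc$qname[j]))
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s|%s|n=%d", best$ms_qname, smc$qname[i], best$n),
          sequence = best$sequence, n = best$n,
          shift_used = best$shift_used, chrom = ch,
          bp = min(smc$bp[i], best$ms_bp),
          ms_qname = best$ms_qname, sm_qname = smc$qname[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Probe-accelerated join: same search as join_pair, but only candidate n
# values implied by an interior 20-mer hit are verified. A pair that
# verifies at more than one n has a periodic (repeat) overlap — the true
# join length is undecidable and concatenating would risk a chimera that
# collapses repeat copies, so the pair is rejected; its raw clipped reads
# still reach the assembly node.
.join_via_probe <- function(sm_seq, ms_seq, read_length, min_n, shift) {
  ns <- .candidate_ns(sm_seq, ms_seq, read_length, min_n)
  lb <- nchar(ms_seq); la <- nchar(sm_seq)
  best <- NULL
  for (n in ns) {
    s <- .match_shift(sm_seq, ms_seq, n, lb, shift)
    if (!is.na(s)) {
      if (!is.null(best)) return(NULL) # ambiguous periodic overlap
      best <- list(n = as.integer(n), shift_used = s,
                   sequence = paste0(ms_seq, substr(sm_seq, n + 1L, la)))
    }
  }
  best
}
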