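#' Sensitivity, precision and F1 from TP/FP/FN counts
#'
#' Sensitivity is true positives over ground-truth events, precision true
#' positives over total called events, and
#' \code{F1 = 2 * sensitivity * precision / (sensitivity + precision)}
#' (0 when both are 0). Precision with no calls at all is reported as 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List of class \code{"sv_eval"}: tp, fp, fn, sensitivity,
#'   precision, f1.
#' @export
sv_metrics <- function(tp, fp, fn) {
  check_that(all(c(tp, fp, fn) >= 0), "counts must be non-negative")
  check_that(tp + fn > 0, "sensitivity undefined: no ground-truth events")
  sens <- tp / (tp + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, f1 = f1_score(sens, prec)),
            class = "sv_eval")
}

#' @rdname sv_metrics
#' @param sensitivity,precision Fractions in [0, 1].
#' @export
f1_score <- function(sensitivity, precision) {
  if (sensitivity + precision == 0) return(0)
  2 * sensitivity * precision / (sensitivity + precision)
}

#' @export
print.sv_eval <- function(x, ...) {
  cat(sprintf(
    "<sv_eval> tp=%d fp=%d fn=%d sensitivity=%.3f precision=%.3f f1=%.3f\n",
    x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$f1))
  invisible(x)
}

#' Match SV calls against a truth set
#'
#' A call matches a truth event of the same type when their breakpoints lie
#' within \code{window} bp (start positions for DEL/INV, anchor points for
#' INS and TRA) and, when both sizes are known, the size difference is
#' strictly below \code{max_size_frac} of the truth size. Size-unknown
#' (imprecise) insertion calls match on the breakpoint window alone, as do
#' translocation breakpoints. Assignment is greedy nearest-first and
#' one-to-one: each truth event absorbs at most one call and extra calls on
#' the same event count as false positives.
#'
#' @param calls,truth Canonical call data.frames of a single SV type.
#' @param svtype One of DEL, INS, INV, TRA.
#' @param window Breakpoint window (bp, default 200).
#' @param max_size_frac Maximum size difference as a fraction of truth size
#'   (default 0.5, strict).
#' @return List: \code{result} (\code{\link{sv_metrics}}),
#'   \code{call_matched} and \code{truth_matched} (index vectors, NA when
#'   unmatched).
#' @export
match_calls <- function(calls, truth, svtype, window = 200L,
                        max_size_frac = 0.5) {
  check_that(svtype %in% c("DEL", "INS", "INV", "TRA"),
             "svtype must be one of DEL, INS, INV, TRA")
  calls <- as_calls(calls); truth <- as_calls(truth)
  check_that(all(calls$svtype == svtype) && all(truth$svtype == svtype),
             "calls/truth mixing SV types; match one type at a time")
  nc <- nrow(calls); nt <- nrow(truth)
  cand <- list()
  for (i in seq_len(nc)) {
    for (j in seq_len(nt)) {
      if (calls$chrom[i] != truth$chrom[j]) next
      d <- abs(calls$pos[i] - truth$pos[j])
      if (d > window) next
      if (svtype != "TRA" && !is.na(calls$size[i]) &&
          !is.na(truth$size[j])) {
        if (abs(calls$size[i] - truth$size[j]) >=
              max_size_frac * truth$size[j]) next
      }
      cand[[length(cand) + 1L]] <- c(i, j, d)
    }
  }
  call_matched <- rep(NA_integer_, nc)
  truth_matched <- rep(NA_integer_, nt)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (is.na(call_matched[i]) && is.na(truth_matched[j])) {
        call_matched[i] <- j
        truth_matched[j] <- i
      }
    }
  }
  tp <- sum(!is.na(truth_matched))
  list(result = sv_metrics(tp = tp, fp = nc - sum(!is.na(call_matched)),
                           fn = nt - tp),
       call_matched = call_matched, truth_matched = truth_matched)
}

#' Relabel tandem duplications as insertions
#'
#' Long-read studies treat tandem duplications as one class of insertion;
#' truth tables are relabeled accordingly before matching.
#'
#' @param truth Canonical call data.frame.
#' @return Same frame with svtype DUP replaced by INS.
#' @export
relabel_duplications <- function(truth) {
  truth$svtype[truth$svtype == "DUP"] <- "INS"
  truth
}

#' Extract an SV truth set from long-read alignments
#'
#' Scans accurate long-read (e.g. HiFi/CCS) alignments: insertions and
#' deletions of at least \code{min_sv} bp are read directly from each
#' CIGAR; split alignments of one read on the same chromosome and strand
#' contribute large deletions (reference gap between colinear segments) or
#' insertions (query gap). Evidence is clustered and clusters supported by
#' at least \code{min_support} distinct reads become truth events.
#'
#' @param bam Long-read BAM path.
#' @param min_support Minimum supporting reads (default 3).
#' @param min_sv Minimum event size (default 50).
#' @return Canonical call data.frame of DEL/INS truth events.
#' @export
longread_truth <- function(bam, min_support = 3L, min_sv = 50L) {
  lens <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  ev <- list()
  for (ch in names(lens)) {
    reads <- scan_reads(bam, ch)
    reads <- reads[reads$primary & !reads$unmapped & !reads$duplicate, ,
                   drop = FALSE]
    if (nrow(reads) == 0) next
    cig <- call_from_cigar(.as_alignment_table(reads), source = "CIGAR_BAM")
    ev[[length(ev) + 1L]] <- cig[cig$size >= min_sv, , drop = FALSE]
    ev[[length(ev) + 1L]] <- .split_gap_evidence(reads, min_sv)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0) return(empty_calls())
  cluster_evidence(ev, X = min_support, min_size = min_sv)
}

# Large DEL/INS implied by a colinear same-strand split alignment.
.split_gap_evidence <- function(reads, min_sv) {
  empty <- data.frame(svtype = character(0), chrom = character(0),
                      pos = integer(0), size = integer(0),
                      source = character(0), query_name = character(0),
                      reads = character(0), stringsAsFactors = FALSE)
  sr <- reads[!is.na(reads$sa), , drop = FALSE]
  if (nrow(sr) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(sr))) {
    sa <- strsplit(sub(";.*$", "", sr$sa[i]), ",", fixed = TRUE)[[1]]
    if (length(sa) != 6L) next
    if (sa[1] != sr$chrom[i]) next
    strand <- ifelse(sr$reverse[i], "-", "+")
    if (sa[3] != strand) next
    # order the two segments by reference position
    p_pos <- sr$pos[i]; s_pos <- as.integer(sa[2])
    p_cig <- sr$cigar[i]; s_cig <- sa[4]
    if (p_pos <= s_pos) {
      left_pos <- p_pos; left_cig <- p_cig
      right_pos <- s_pos; right_cig <- s_cig
    } else {
      left_pos <- s_pos; left_cig <- s_cig
      right_pos <- p_pos; right_cig <- p_cig
    }
    left_end <- left_pos +
      GenomicAlignments::cigarWidthAlongReferenceSpace(left_cig)
    ref_gap <- right_pos - left_end
    # query gap: unaligned query between the two segments
    lcl <- terminal_clip_lengths(left_cig)
    rcl <- terminal_clip_lengths(right_cig)
    lq <- GenomicAlignments::cigarWidthAlongQuerySpace(
      left_cig, after.soft.clipping = TRUE)
    query_gap <- rcl$lead - (lcl$lead + lq)
    if (ref_gap >= min_sv && ref_gap > query_gap) {
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = "DEL", chrom = sr$chrom[i], pos = as.integer(left_end),
        size = as.integer(ref_gap - max(0L, query_gap)),
        source = "SPLIT_LR", query_name = sr$qname[i], reads = sr$qname[i],
        stringsAsFactors = FALSE)
    } else if (query_gap >= min_sv && query_gap > ref_gap) {
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = "INS", chrom = sr$chrom[i], pos = as.integer(left_end),
        size = as.integer(query_gap - max(0L, ref_gap)),
        source = "SPLIT_LR", query_name = sr$qname[i], reads = sr$qname[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Fraction of truth events captured by one read-signal category
#'
#' Clipped and split reads provide exact breakpoint sites: sites confirmed
#' by at least two reads within 5 bp capture a truth event lying within
#' \code{window} bp (200). Discordant, mate-unmapped and cross-chromosome
#' pair signals only bracket the event: approximate sites are placed 200 bp
#' outside each read boundary, confirmed by two reads within 200 bp, and
#' capture events within \code{wide_window} bp (600).
#'
#' @param reads Classified read frame (\code{\link{classify_reads}}).
#' @param truth Canonical truth calls (one SV type or mixed).
#' @param category One of CLIPPED, SPLIT, DISCORDANT, TRANSLOCATION_PAIR,
#'   MATE_UNMAPPED.
#' @param config \code{\link{caller_config}}.
#' @param window,wide_window Capture windows (bp).
#' @return Fraction of truth events captured.
#' @export
signal_capture <- function(reads, truth, category,
                           config = caller_config(), window = 200L,
                           wide_window = 600L) {
  if (nrow(truth) == 0) return(NA_real_)
  exact <- category %in% c("CLIPPED", "SPLIT")
  if (exact) {
    if (category == "CLIPPED") {
      clips <- extract_clips(reads, config)
      sites <- clips[, c("chrom", "bp")]
    } else {
      sr <- reads[reads$sig_split & reads$primary, , drop = FALSE]
      sites <- data.frame(chrom = sr$chrom,
                          bp = .junction_point(sr$cigar, sr$pos),
                          stringsAsFactors = FALSE)
    }
    confirmed <- .confirmed_sites(sites, tol = 5L)
    win <- window
  } else {
    flagcol <- switch(category, DISCORDANT = "sig_discordant",
                      TRANSLOCATION_PAIR = "sig_tra_pair",
                      MATE_UNMAPPED = "sig_mate_unmapped",
                      stop("unknown category: ", category))
    rr <- reads[reads[[flagcol]] & reads$primary & !reads$unmapped, ,
                drop = FALSE]
    if (nrow(rr) == 0) return(0)
    refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(rr$cigar)
    sites <- data.frame(
      chrom = rep(rr$chrom, 2L),
      bp = c(rr$pos - 200L, rr$pos + refw + 200L),
      stringsAsFactors = FALSE)
    confirmed <- .confirmed_sites(sites, tol = 200L)
    win <- wide_window
  }
  if (nrow(confirmed) == 0) return(0)
  captured <- vapply(seq_len(nrow(truth)), function(j) {
    any(confirmed$chrom == truth$chrom[j] &
          abs(confirmed$bp - truth$pos[j]) <= win)
  }, logical(1))
  mean(captured)
}

# Sites supported by >= 2 reads within `tol` bp.
.confirmed_sites <- function(sites, tol) {
  out <- data.frame(chrom = character(0), bp = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(out)
  res <- list()
  for (ch in unique(sites$chrom)) {
    bp <- sort(sites$bp[sites$chrom == ch])
    i <- 1L
    while (i <= length(bp)) {
      j <- i
      while (j < length(bp) && bp[j + 1L] - bp[i] <= tol) j <- j + 1L
      if (j > i) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, bp = as.integer(round(median(bp[i:j]))),
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (length(res) == 0) return(out)
  do.call(rbind, res)
}
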