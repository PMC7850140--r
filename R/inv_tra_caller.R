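#' Call inversions from split reads and same-orientation pairs
#'
#' Two evidence channels:
#' \describe{
#'   \item{split}{a read whose primary and supplementary (SA tag)
#'     alignments sit on the same chromosome with opposite orientations
#'     supports an inversion spanning the two junction points. The primary
#'     junction is the clip boundary on the clipped side; the supplementary
#'     junction is its reference boundary on its own clipped side, read
#'     from the SA CIGAR.}
#'   \item{pair}{a proper-length read pair aligned with the same
#'     orientation supports a larger inversion. Its breakpoints are
#'     estimated from the observed span and the expected insert size
#'     (outer-mate positions moved outward by half the insert deficit) and
#'     are imprecise until snapped.}
#' }
#' Every estimated breakpoint within \code{match_window} bp of a clipped-read
#' breakpoint is snapped to that exact position. Snapped evidence is
#' clustered with the standard position/size tolerances, and clusters
#' supported by at least X reads (split and pair evidence may mix) become
#' inversion calls.
#'
#' @param reads Read frame with \code{sig_*} columns
#'   (\code{\link{classify_reads}}).
#' @param clips Quality-filtered clip frame, used for snapping.
#' @param stats \code{insert_stats}.
#' @param X Support threshold.
#' @param config \code{\link{caller_config}}.
#' @return Canonical call data.frame of INV records.
#' @export
call_inversions <- function(reads, clips, stats, X,
                            config = caller_config()) {
  ev <- list()
  sp <- .split_evidence(reads, same_chrom = TRUE, config)
  if (nrow(sp)) {
    sp <- sp[sp$strand1 != sp$strand2, , drop = FALSE]
    if (nrow(sp)) {
      ev$split <- data.frame(
        chrom = sp$chrom1, left = pmin(sp$p1, sp$p2),
        right = pmax(sp$p1, sp$p2), qname = sp$qname, src = "SPLIT",
        stringsAsFactors = FALSE)
    }
  }
  pr <- reads[reads$sig_inv_pair & reads$primary & !reads$duplicate &
                !is.na(reads$mate_pos) & reads$pos <= reads$mate_pos &
                reads$mapq >= config$min_mapq, , drop = FALSE]
  if (nrow(pr)) {
    span_end <- pr$mate_pos + stats$read_length
    span <- span_end - pr$pos
    slack <- pmax(0, round((stats$mean - span) / 2))
    ev$pair <- data.frame(
      chrom = pr$chrom, left = as.integer(pr$pos - slack),
      right = as.integer(span_end + slack), qname = pr$qname, src = "PAIR",
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0) return(empty_calls())
  ev$left <- .snap_to_clips(ev$chrom, ev$left, clips, config$match_window)
  ev$right <- .snap_to_clips(ev$chrom, ev$right, clips,
                             config$match_window)
  ok <- ev$right - ev$left >= 1L
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) return(empty_calls())
  evidence <- data.frame(svtype = "INV", chrom = ev$chrom, pos = ev$left,
                         size = ev$right - ev$left, source = ev$src,
                         query_name = ev$qname, reads = ev$qname,
                         stringsAsFactors = FALSE)
  calls <- cluster_evidence(evidence, X = X, min_size = config$min_sv,
                            pos_tol = config$cluster_pos_tol,
                            size_tol = config$cluster_size_tol)
  if (nrow(calls)) calls$evidence <- "INV_READS"
  .merge_overlapping_inversions(calls)
}

# Pair-derived breakpoint estimates can snap to different clipped reads and
# fragment one inversion into several clusters; calls with >= 50% reciprocal
# overlap collapse onto the best-supported one.
.merge_overlapping_inversions <- function(calls) {
  if (nrow(calls) <= 1) return(calls)
  ord <- order(-calls$support, calls$pos)
  keep <- logical(nrow(calls))
  for (i in ord) {
    kept <- which(keep)
    clash <- FALSE
    for (j in kept) {
      if (calls$chrom[i] != calls$chrom[j]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$pos[i], calls$pos[j])
      if (ov > 0 && ov >= 0.5 * max(calls$size[i], calls$size[j])) {
        clash <- TRUE
        break
      }
    }
    keep[i] <- !clash
  }
  sort_calls(calls[keep, , drop = FALSE])
}

#' Call translocations from cross-chromosome evidence
#'
#' Split reads whose primary and supplementary alignments sit on different
#' chromosomes give exact junction points, provided both sides exceed
#' mapping quality \code{tra_mapq}; cross-chromosome read pairs give
#' approximate junctions near the outer read boundaries, refined by
#' snapping to clipped-read breakpoints. Evidence joining the same
#' chromosome pair is clustered on the first-chromosome junction; a cluster
#' needs combined split + pair support of at least \code{2X} to be emitted,
#' as a reciprocal pair of breakend (BND) records.
#'
#' @inheritParams call_inversions
#' @return Canonical call data.frame of paired BND (svtype "TRA") records.
#' @export
call_translocations <- function(reads, clips, X, config = caller_config()) {
  ev <- list()
  sp <- .split_evidence(reads, same_chrom = FALSE, config)
  if (nrow(sp)) {
    sp <- sp[sp$mapq1 > config$tra_mapq & sp$mapq2 > config$tra_mapq, ,
             drop = FALSE]
    if (nrow(sp)) {
      ev$split <- data.frame(chrom1 = sp$chrom1, p1 = sp$p1,
                             chrom2 = sp$chrom2, p2 = sp$p2,
                             qname = sp$qname, src = "SPLIT",
                             stringsAsFactors = FALSE)
    }
  }
  # each pair may appear through either mate (or both, in different
  # chunks); distinct-qname support counting dedupes
  pr <- reads[reads$sig_tra_pair & reads$primary & !reads$duplicate &
                reads$mapq >= config$min_mapq, , drop = FALSE]
  if (nrow(pr)) {
    refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(pr$cigar)
    p1 <- as.integer(ifelse(pr$reverse, pr$pos, pr$pos + refw))
    ev$pair <- data.frame(chrom1 = pr$chrom, p1 = p1,
                          chrom2 = pr$mate_chrom,
                          p2 = as.integer(pr$mate_pos),
                          qname = pr$qname, src = "PAIR",
                          stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0) return(empty_calls())
  # canonical chromosome order within each evidence row
  flip <- ev$chrom1 > ev$chrom2
  if (any(flip)) {
    tmp <- ev[flip, ]
    ev[flip, c("chrom1", "p1")] <- tmp[, c("chrom2", "p2")]
    ev[flip, c("chrom2", "p2")] <- tmp[, c("chrom1", "p1")]
  }
  ev$p1 <- .snap_to_clips(ev$chrom1, ev$p1, clips, config$match_window)
  ev$p2 <- .snap_to_clips(ev$chrom2, ev$p2, clips, config$match_window)
  rows <- list()
  for (key in unique(paste(ev$chrom1, ev$chrom2))) {
    sub <- ev[paste(ev$chrom1, ev$chrom2) == key, , drop = FALSE]
    sub <- sub[order(sub$p1), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(sub$p1) > config$match_window))
    for (g in unique(grp)) {
      cl <- sub[grp == g, , drop = FALSE]
      supp <- length(unique(cl$qname))
      if (supp < 2L * X) next
      snapped1 <- cl$p1[cl$src == "SPLIT"]
      snapped2 <- cl$p2[cl$src == "SPLIT"]
      pos1 <- if (length(snapped1)) median(snapped1) else median(cl$p1)
      pos2 <- if (length(snapped2)) median(snapped2) else median(cl$p2)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cl$chrom1[1], pos = as.integer(round(pos1)),
        partner_chrom = cl$chrom2[1], partner_pos = as.integer(round(pos2)),
        support = supp, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_calls())
  df <- do.call(rbind, rows)
  out <- list()
  for (i in seq_len(nrow(df))) {
    ida <- sprintf("TRA%d_1", i); idb <- sprintf("TRA%d_2", i)
    out[[2 * i - 1]] <- data.frame(
      chrom = df$chrom[i], pos = df$pos[i], svtype = "TRA",
      support = df$support[i], evidence = "TRA_READS",
      partner_chrom = df$partner_chrom[i], partner_pos = df$partner_pos[i],
      id = ida, mate_id = idb, stringsAsFactors = FALSE)
    out[[2 * i]] <- data.frame(
      chrom = df$partner_chrom[i], pos = df$partner_pos[i], svtype = "TRA",
      support = df$support[i], evidence = "TRA_READS",
      partner_chrom = df$chrom[i], partner_pos = df$pos[i],
      id = idb, mate_id = ida, stringsAsFactors = FALSE)
  }
  sort_calls(as_calls(do.call(rbind, out)))
}

# Junction pairs from SA-tagged primary alignments. The junction of each
# side is the reference boundary adjacent to its larger clip.
.split_evidence <- function(reads, same_chrom, config) {
  empty <- data.frame(qname = character(0), chrom1 = character(0),
                      p1 = integer(0), strand1 = character(0),
                      mapq1 = integer(0), chrom2 = character(0),
                      p2 = integer(0), strand2 = character(0),
                      mapq2 = integer(0), stringsAsFactors = FALSE)
  sr <- reads[reads$sig_split & reads$primary & !reads$duplicate, ,
              drop = FALSE]
  if (nrow(sr) == 0) return(empty)
  sa <- strsplit(sub(";.*$", "", sr$sa), ",", fixed = TRUE)
  okl <- vapply(sa, length, integer(1)) == 6L
  sr <- sr[okl, , drop = FALSE]; sa <- sa[okl]
  if (nrow(sr) == 0) return(empty)
  sa_chrom <- vapply(sa, `[[`, character(1), 1)
  sa_pos <- as.integer(vapply(sa, `[[`, character(1), 2))
  sa_strand <- vapply(sa, `[[`, character(1), 3)
  sa_cigar <- vapply(sa, `[[`, character(1), 4)
  sa_mapq <- as.integer(vapply(sa, `[[`, character(1), 5))
  same <- sa_chrom == sr$chrom
  keep <- if (same_chrom) same else !same
  if (!any(keep)) return(empty)
  sr <- sr[keep, , drop = FALSE]
  sa_chrom <- sa_chrom[keep]; sa_pos <- sa_pos[keep]
  sa_strand <- sa_strand[keep]; sa_cigar <- sa_cigar[keep]
  sa_mapq <- sa_mapq[keep]
  p1 <- .junction_point(sr$cigar, sr$pos)
  p2 <- .junction_point(sa_cigar, sa_pos)
  data.frame(qname = sr$qname, chrom1 = sr$chrom, p1 = p1,
             strand1 = ifelse(sr$reverse, "-", "+"), mapq1 = sr$mapq,
             chrom2 = sa_chrom, p2 = p2, strand2 = sa_strand,
             mapq2 = sa_mapq, stringsAsFactors = FALSE)
}

# Reference boundary adjacent to the larger terminal clip of an alignment.
.junction_point <- function(cigar, pos) {
  cl <- terminal_clip_lengths(cigar)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  as.integer(ifelse(cl$trail >= cl$lead, pos + refw, pos))
}

# Snap positions to the nearest clipped-read breakpoint within `window`.
.snap_to_clips <- function(chrom, pos, clips, window) {
  if (is.null(clips) || nrow(clips) == 0) return(as.integer(pos))
  out <- as.integer(pos)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bps <- sort(unique(clips$bp[clips$chrom == ch]))
    if (length(bps) == 0) next
    nearest <- findInterval(out[idx], bps)
    lo <- pmax(nearest, 1L)
    hi <- pmin(nearest + 1L, length(bps))
    d_lo <- abs(out[idx] - bps[lo])
    d_hi <- abs(out[idx] - bps[hi])
    best <- ifelse(d_hi < d_lo, bps[hi], bps[lo])
    d <- pmin(d_lo, d_hi)
    out[idx] <- ifelse(d <= window, best, out[idx])
  }
  out
}
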