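#' Classify imperfect alignments into SV signal categories
#'
#' Adds one logical column per signal category to the read frame:
#' \describe{
#'   \item{sig_clipped}{any terminal clip strictly longer than
#'     \code{min_clip} (soft or hard);}
#'   \item{sig_split}{an SA (supplementary alignment) tag is present;}
#'   \item{sig_discordant}{mates on the same chromosome with
#'     \code{|TLEN| > min(mean + sd, mean + discordant_pad)};}
#'   \item{sig_tra_pair}{mates aligned to different chromosomes;}
#'   \item{sig_inv_pair}{both mates mapped to the same chromosome in the
#'     same orientation;}
#'   \item{sig_mate_unmapped}{the mate-unmapped flag is set.}
#' }
#' Unmapped records receive no category. A read may carry several
#' categories at once.
#'
#' @param reads data.frame from \code{\link{scan_reads}} (primary,
#'   non-duplicate records are the intended input).
#' @param stats \code{insert_stats} for the region.
#' @param config \code{\link{caller_config}}.
#' @return \code{reads} with the six \code{sig_*} columns appended.
#' @export
classify_reads <- function(reads, stats, config = caller_config()) {
  n <- nrow(reads)
  mapped <- !reads$unmapped
  both_mapped <- mapped & reads$paired & !reads$mate_unmapped
  same_chrom <- both_mapped & !is.na(reads$mate_chrom) &
    reads$mate_chrom == reads$chrom
  clip_lens <- terminal_clip_lengths(reads$cigar)
  thresh <- min(stats$mean + stats$sd, stats$mean + config$discordant_pad)

  reads$sig_clipped <- mapped &
    pmax(clip_lens$lead, clip_lens$trail) > config$min_clip
  reads$sig_split <- mapped & !is.na(reads$sa)
  reads$sig_discordant <- same_chrom & !is.na(reads$tlen) &
    abs(reads$tlen) > thresh
  reads$sig_tra_pair <- both_mapped & !is.na(reads$mate_chrom) &
    reads$mate_chrom != reads$chrom
  reads$sig_inv_pair <- same_chrom & reads$reverse == reads$mate_reverse
  reads$sig_mate_unmapped <- mapped & reads$paired & reads$mate_unmapped
  reads
}

#' @rdname classify_reads
#' @param read A single-row read frame.
#' @return For \code{classify_read}: character vector of category names
#'   (subset of CLIPPED, SPLIT, DISCORDANT, TRANSLOCATION_PAIR,
#'   INVERSION_PAIR, MATE_UNMAPPED).
#' @export
classify_read <- function(read, stats, config = caller_config()) {
  r <- classify_reads(read, stats, config)
  nm <- c(sig_clipped = "CLIPPED", sig_split = "SPLIT",
          sig_discordant = "DISCORDANT", sig_tra_pair = "TRANSLOCATION_PAIR",
          sig_inv_pair = "INVERSION_PAIR", sig_mate_unmapped = "MATE_UNMAPPED")
  unname(nm[vapply(names(nm), function(col) isTRUE(r[[col]][1]), logical(1))])
}

# Total clip length at each read end (H + S ops; H is outermost by SAM).
# NA/"*" CIGARs (unmapped records) count as unclipped.
terminal_clip_lengths <- function(cigar) {
  cigar[is.na(cigar) | cigar == "*" | cigar == ""] <- "1M"
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- integer(length(cigar))
  trail <- integer(length(cigar))
  soft_lead <- integer(length(cigar))
  soft_trail <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    o <- ops[[i]]; l <- lens[[i]]
    k <- length(o)
    if (k == 0) next
    j <- 1L
    while (j <= k && o[j] %in% c("H", "S")) {
      lead[i] <- lead[i] + l[j]
      if (o[j] == "S") soft_lead[i] <- soft_lead[i] + l[j]
      j <- j + 1L
    }
    j <- k
    while (j >= 1L && o[j] %in% c("H", "S")) {
      trail[i] <- trail[i] + l[j]
      if (o[j] == "S") soft_trail[i] <- soft_trail[i] + l[j]
      j <- j - 1L
    }
    if (lead[i] + trail[i] > sum(l)) { # fully clipped degenerate record
      trail[i] <- 0L; soft_trail[i] <- 0L
    }
  }
  list(lead = lead, trail = trail, soft_lead = soft_lead,
       soft_trail = soft_trail)
}

#' Extract clipped-read records
#'
#' One record per clipped read end with clip length strictly greater than
#' \code{min_clip}. A read clipped at its 5' end (alignment starts with a
#' clip) yields an SM record whose breakpoint is the first aligned base; a
#' read clipped at its 3' end yields an MS record whose breakpoint is one
#' past the last aligned base. Base qualities are summarized separately for
#' the mapped and the clipped query segments as high-quality-base ratios
#' (Phred > 20). Hard-clipped ends have no stored sequence: their
#' \code{clipped_seq} is empty and they cannot seed extension, but they
#' still count as breakpoint support.
#'
#' @param reads data.frame from \code{\link{scan_reads}}; secondary and
#'   duplicate records are ignored.
#' @param config \code{\link{caller_config}}.
#' @return data.frame with one row per clipped end: qname, chrom, side
#'   ("MS"/"SM"), bp, clip_len, clipped_seq, read_seq, mapq, mapped_hq,
#'   clipped_hq, supplementary, mate_unmapped, mate_chrom.
#' @export
extract_clips <- function(reads, config = caller_config()) {
  reads <- reads[!reads$unmapped & !reads$secondary & !reads$duplicate &
                   !is.na(reads$cigar) & grepl("[SH]", reads$cigar), ,
                 drop = FALSE]
  out <- list(
    qname = character(0), chrom = character(0), side = character(0),
    bp = integer(0), clip_len = integer(0), clipped_seq = character(0),
    read_seq = character(0), mapq = integer(0), mapped_hq = numeric(0),
    clipped_hq = numeric(0), supplementary = logical(0),
    mate_unmapped = logical(0), mate_chrom = character(0)
  )
  if (nrow(reads) == 0) return(as.data.frame(out, stringsAsFactors = FALSE))
  cl <- terminal_clip_lengths(reads$cigar)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  rows <- list()
  add <- function(i, side, bp, clip_len, soft_len, at_start) {
    seq <- reads$seq[i]
    quals <- phred_vector(reads$qual[i])
    qlen <- nchar(seq)
    # mapped query segment excludes soft clips at both ends
    m_from <- cl$soft_lead[i] + 1L
    m_to <- qlen - cl$soft_trail[i]
    mapped_hq <- if (length(quals) && m_from <= m_to)
      hq_base_ratio(quals, m_from, m_to) else NA_real_
    if (soft_len > 0) {
      if (at_start) { c_from <- 1L; c_to <- soft_len }
      else { c_from <- qlen - soft_len + 1L; c_to <- qlen }
      cseq <- substr(seq, c_from, c_to)
      chq <- if (length(quals)) hq_base_ratio(quals, c_from, c_to)
             else NA_real_
    } else {
      cseq <- ""; chq <- NA_real_
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      qname = reads$qname[i], chrom = reads$chrom[i], side = side,
      bp = as.integer(bp), clip_len = as.integer(clip_len),
      clipped_seq = cseq, read_seq = seq, mapq = reads$mapq[i],
      mapped_hq = mapped_hq, clipped_hq = chq,
      supplementary = reads$supplementary[i],
      mate_unmapped = reads$mate_unmapped[i],
      mate_chrom = reads$mate_chrom[i],
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(reads))) {
    if (cl$lead[i] > config$min_clip) {
      add(i, "SM", reads$pos[i], cl$lead[i], cl$soft_lead[i], TRUE)
    }
    if (cl$trail[i] > config$min_clip) {
      add(i, "MS", reads$pos[i] + refw[i], cl$trail[i], cl$soft_trail[i],
          FALSE)
    }
  }
  if (length(rows) == 0) return(as.data.frame(out, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Collect candidate SV breakpoints from clipped reads
#'
#' Greedy left-to-right sweep over sorted clip breakpoints: positions within
#' a 5 bp diameter of the first member join the cluster. The representative
#' position is the mode of member positions (ties broken leftmost); clusters
#' supported by fewer than \code{X} clipped reads are dropped. Input is
#' expected to be the quality-filtered clip set (mapping quality >= 20,
#' non-supplementary).
#'
#' @param clips data.frame from \code{\link{extract_clips}}.
#' @param X Support threshold (see \code{\link{support_threshold}}).
#' @param window Cluster diameter in bp (default 5).
#' @return data.frame: chrom, pos, support, n_ms, n_sm, sorted by position.
#' @export
collect_candidate_breakpoints <- function(clips, X, window = 5L) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    support = integer(0), n_ms = integer(0),
                    n_sm = integer(0), stringsAsFactors = FALSE)
  if (nrow(clips) == 0) return(out)
  res <- list()
  for (ch in sort(unique(clips$chrom))) {
    cc <- clips[clips$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$bp), , drop = FALSE]
    i <- 1L
    while (i <= nrow(cc)) {
      first <- cc$bp[i]
      j <- i
      while (j < nrow(cc) && cc$bp[j + 1L] - first <= window) j <- j + 1L
      members <- cc[i:j, , drop = FALSE]
      if (nrow(members) >= X) {
        tab <- table(members$bp)
        rep_pos <- as.integer(names(tab)[which.max(tab)])
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, pos = rep_pos, support = nrow(members),
          n_ms = sum(members$side == "MS"),
          n_sm = sum(members$side == "SM"), stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (length(res) == 0) return(out)
  df <- do.call(rbind, res)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Quality filter shared by extension, candidate collection and assembly.
filter_clips <- function(clips, config = caller_config()) {
  clips[clips$mapq >= config$min_mapq & !clips$supplementary, ,
        drop = FALSE]
}
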