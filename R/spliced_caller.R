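#' Spliced (large-gap) alignment of query sequences
#'
#' Aligns each query against a local reference window allowing large
#' reference gaps (deletion junctions) and query gaps (insertions), the
#' alignment mode originally built for exon/intron structure and used here
#' to read SV junctions out of reconstructed long sequences. Two backends:
#' \describe{
#'   \item{builtin}{exact 15-mer seeding against the window, merging of
#'     co-diagonal seeds into segments, colinear segment chaining, and CIGAR
#'     emission with a D op for a reference gap and an I op for a query gap
#'     between adjacent chain segments. Terminal segments are extended
#'     outward base-by-base while query and reference agree; up to 3
#'     remaining terminal bases are absorbed into the terminal match block
#'     (mirroring affine end alignment), anything longer is soft-clipped.}
#'   \item{minimap2}{shells out to the minimap2 binary in spliced mode and
#'     parses its SAM output.}
#' }
#'
#' @param queries Named character vector of query sequences.
#' @param ref_seq Reference window sequence (character) or a
#'   \code{DNAString}.
#' @param chrom Chromosome name of the window.
#' @param window_start 1-based chromosome coordinate of
#'   \code{ref_seq[1]}.
#' @param backend \code{"builtin"} (default) or \code{"minimap2"}.
#' @param k Seed length for the builtin backend.
#' @return data.frame of alignments: query_name, chrom, pos, mapq, cigar,
#'   n_segments, boundary_clipped, boundary_aligned_len, aligned_frac.
#'   Queries with no seed hit are reported unaligned (absent).
#' @export
spliced_align <- function(queries, ref_seq, chrom, window_start = 1L,
                          backend = c("builtin", "minimap2"), k = 15L) {
  backend <- match.arg(backend)
  if (length(queries) == 0) return(.empty_alignments())
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- sprintf("query_%d", seq_along(queries))
  }
  if (backend == "minimap2") {
    return(.spliced_align_minimap2(queries, ref_seq, chrom, window_start))
  }
  subject_str <- toupper(as.character(ref_seq))
  subject_chars <- strsplit(subject_str, "")[[1]]
  index <- .window_index(subject_str, k)
  rows <- lapply(seq_along(queries), function(i) {
    .align_one(names(queries)[i], queries[[i]], index, subject_chars,
               chrom, window_start, k)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(.empty_alignments())
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

.empty_alignments <- function() {
  data.frame(query_name = character(0), chrom = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             n_segments = integer(0), boundary_clipped = logical(0),
             boundary_aligned_len = integer(0), aligned_frac = numeric(0),
             stringsAsFactors = FALSE)
}

# Hash index of window k-mer positions; hyper-repetitive k-mers (> 20
# occurrences) are masked out.
.window_index <- function(subject_str, k) {
  n <- nchar(subject_str)
  if (n < k) return(emptyenv())
  km <- substring(subject_str, 1:(n - k + 1L), k:n)
  by_kmer <- split(seq_len(n - k + 1L), km)
  by_kmer <- by_kmer[lengths(by_kmer) <= 20L]
  list2env(by_kmer, hash = TRUE, size = length(by_kmer))
}

# Seed, merge co-diagonal runs, chain, emit one alignment row (or NULL).
.align_one <- function(qname, qseq, index, subject_chars, chrom,
                       window_start, k) {
  lq <- nchar(qseq)
  if (lq < k) return(NULL)
  qk <- substring(toupper(qseq), 1:(lq - k + 1L), k:lq)
  hits <- mget(qk, envir = index, ifnotfound = list(integer(0)))
  qpos <- rep(seq_along(qk), lengths(hits))
  rpos <- unlist(hits, use.names = FALSE)
  if (length(qpos) == 0) return(NULL)
  segs <- .merge_diagonal_runs(qpos, rpos, k)
  chain <- .chain_segments(segs, k)
  if (is.null(chain)) return(NULL)
  .emit_cigar(qname, qseq, subject_chars, chain, k, chrom, window_start)
}

# Seeds sharing a diagonal (rpos - qpos) with query gaps <= 100 bp merge
# into one segment covering query [qs, qe + k - 1].
.merge_diagonal_runs <- function(qpos, rpos, k, max_gap = 100L) {
  d <- rpos - qpos
  ord <- order(d, qpos)
  qpos <- qpos[ord]; rpos <- rpos[ord]; d <- d[ord]
  new_seg <- c(TRUE, diff(d) != 0L | diff(qpos) > max_gap)
  id <- cumsum(new_seg)
  qs <- tapply(qpos, id, min); qe <- tapply(qpos, id, max)
  rs <- tapply(rpos, id, min)
  ns <- tapply(qpos, id, length)
  data.frame(qs = as.integer(qs), qe = as.integer(qe),
             rs = as.integer(rs), d = as.integer(rs - qs),
             n_seeds = as.integer(ns))
}

# Colinear chaining over segments: maximize covered query bases, preferring
# small coordinate gaps. Returns the chained segments in query order.
.chain_segments <- function(segs, k, max_gap = 60000L) {
  segs <- segs[order(segs$qs, segs$rs), , drop = FALSE]
  m <- nrow(segs)
  cover <- segs$qe - segs$qs + k
  score <- cover
  prev <- rep(NA_integer_, m)
  if (m > 1) {
    for (i in 2:m) {
      for (j in 1:(i - 1)) {
        if (segs$qs[i] > segs$qs[j] && segs$qe[i] > segs$qe[j] &&
            segs$rs[i] > segs$rs[j]) {
          gap <- abs((segs$rs[i] - segs$rs[j]) - (segs$qs[i] - segs$qs[j]))
          if (gap > max_gap) next
          overlap <- max(0L, segs$qe[j] + k - segs$qs[i])
          s <- score[j] + cover[i] - overlap - 1e-4 * gap
          if (s > score[i]) { score[i] <- s; prev[i] <- j }
        }
      }
    }
  }
  best <- which.max(score)
  idx <- best
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  segs[idx, , drop = FALSE]
}

.emit_cigar <- function(qname, qseq, subject_chars, chain, k, chrom,
                        window_start) {
  ls <- length(subject_chars)
  lq <- nchar(qseq)
  qc <- strsplit(qseq, "")[[1]]
  m <- nrow(chain)
  # trim overlapping neighbours (shared query or reference bases) off the
  # left segment's end, so placement-ambiguous gaps come out left-aligned
  qstart <- chain$qs
  qend <- chain$qe + k - 1L
  rstart <- chain$rs
  if (m > 1) {
    for (i in 2:m) {
      rend_prev <- rstart[i - 1L] + (qend[i - 1L] - qstart[i - 1L])
      trim <- max(qend[i - 1L] - qstart[i] + 1L,
                  rend_prev - rstart[i] + 1L, 0L)
      qend[i - 1L] <- qend[i - 1L] - trim
      if (qend[i - 1L] < qstart[i - 1L]) return(NULL) # degenerate chain
    }
  }
  rend <- rstart + (qend - qstart)
  # extend first segment leftward, last rightward, while bases agree
  while (qstart[1] > 1L && rstart[1] > 1L &&
         qc[qstart[1] - 1L] == subject_chars[rstart[1] - 1L]) {
    qstart[1] <- qstart[1] - 1L; rstart[1] <- rstart[1] - 1L
  }
  while (qend[m] < lq && rend[m] < ls &&
         qc[qend[m] + 1L] == subject_chars[rend[m] + 1L]) {
    qend[m] <- qend[m] + 1L; rend[m] <- rend[m] + 1L
  }
  # absorb short mismatched termini into the terminal match blocks
  lead <- qstart[1] - 1L
  if (lead > 0L && lead <= 3L && rstart[1] - lead >= 1L) {
    qstart[1] <- 1L; rstart[1] <- rstart[1] - lead; lead <- 0L
  }
  trail <- lq - qend[m]
  if (trail > 0L && trail <= 3L && rend[m] + trail <= ls) {
    qend[m] <- lq; rend[m] <- rend[m] + trail; trail <- 0L
  }
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + len
    } else {
      ops <<- c(ops, op); lens <<- c(lens, len)
    }
  }
  push("S", lead)
  push("M", qend[1] - qstart[1] + 1L)
  if (m > 1) {
    for (i in 2:m) {
      gq <- qstart[i] - qend[i - 1L] - 1L
      gr <- rstart[i] - rend[i - 1L] - 1L
      if (gq < 0L || gr < 0L) return(NULL)
      push("M", min(gq, gr))
      if (gr > gq) push("D", gr - gq)
      if (gq > gr) push("I", gq - gr)
      push("M", qend[i] - qstart[i] + 1L)
    }
  }
  push("S", trail)
  aligned <- sum(lens[ops == "M"])
  mblocks <- lens[ops == "M"]
  data.frame(
    query_name = qname, chrom = chrom,
    pos = as.integer(window_start + rstart[1] - 1L),
    mapq = 60L,
    cigar = paste0(lens, ops, collapse = ""),
    n_segments = 1L,
    boundary_clipped = ops[1] == "S" || ops[length(ops)] == "S",
    boundary_aligned_len = as.integer(min(mblocks[1],
                                          mblocks[length(mblocks)])),
    aligned_frac = aligned / lq,
    stringsAsFactors = FALSE
  )
}

# External backend: minimap2 spliced mode over a window FASTA.
.spliced_align_minimap2 <- function(queries, ref_seq, chrom, window_start) {
  if (Sys.which("minimap2") == "") {
    stop("minimap2 binary not found on PATH; use backend = \"builtin\"",
         call. = FALSE)
  }
  td <- tempfile("mm2"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  reff <- file.path(td, "window.fa")
  qf <- file.path(td, "queries.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(ref_seq), "window")),
    reff)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(queries), qf)
  samf <- file.path(td, "out.sam")
  status <- system2("minimap2",
                    c("-a", "-x", "splice", "-u", "n", "--secondary=no",
                      "-G", "60k", reff, qf),
                    stdout = samf, stderr = FALSE)
  check_that(status == 0, "minimap2 failed")
  sam <- readLines(samf)
  sam <- sam[!startsWith(sam, "@")]
  if (length(sam) == 0) return(.empty_alignments())
  fields <- strsplit(sam, "\t")
  qn <- vapply(fields, `[[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  pos <- as.integer(vapply(fields, `[[`, character(1), 4))
  mapq <- as.integer(vapply(fields, `[[`, character(1), 5))
  cigar <- vapply(fields, `[[`, character(1), 6)
  mapped <- !flag_bit(flag, 0x4)
  nseg <- table(qn[mapped])
  keep <- mapped & !flag_bit(flag, 0x100) & !flag_bit(flag, 0x800)
  if (!any(keep)) return(.empty_alignments())
  cl <- terminal_clip_lengths(cigar[keep])
  mlens <- .terminal_match_lengths(cigar[keep])
  data.frame(
    query_name = qn[keep], chrom = chrom,
    pos = as.integer(window_start + pos[keep] - 1L),
    mapq = mapq[keep], cigar = cigar[keep],
    n_segments = as.integer(nseg[qn[keep]]),
    boundary_clipped = cl$lead > 0L | cl$trail > 0L,
    boundary_aligned_len = mlens,
    aligned_frac = GenomicAlignments::cigarWidthAlongQuerySpace(
      cigar[keep], after.soft.clipping = TRUE) /
      GenomicAlignments::cigarWidthAlongQuerySpace(cigar[keep]),
    stringsAsFactors = FALSE
  )
}

# Shortest terminal aligned (M/=/X) block length per CIGAR.
.terminal_match_lengths <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  vapply(seq_along(cigar), function(i) {
    keep <- ops[[i]] %in% c("M", "=", "X")
    if (!any(keep)) return(0L)
    ml <- lens[[i]][keep]
    as.integer(min(ml[1], ml[length(ml)]))
  }, integer(1))
}

#' Filter spliced alignments
#'
#' Drops low-quality spliced alignments before SV evidence extraction:
#' mapping quality below 10, clipped boundary sequence, terminal aligned
#' block shorter than 20 bp, or a query fragmented into more than five
#' separately aligned regions.
#'
#' @param alns data.frame from \code{\link{spliced_align}}.
#' @param min_mapq,min_boundary,max_segments Thresholds (defaults 10, 20,
#'   5).
#' @return \code{alns} with logical \code{keep} and character
#'   \code{drop_reason} columns appended.
#' @export
filter_alignments <- function(alns, min_mapq = 10L, min_boundary = 20L,
                              max_segments = 5L) {
  reason <- rep(NA_character_, nrow(alns))
  reason[alns$n_segments > max_segments] <- "fragmented"
  reason[alns$boundary_aligned_len < min_boundary] <- "short_boundary"
  reason[alns$boundary_clipped] <- "boundary_clipped"
  reason[alns$mapq < min_mapq] <- "low_mapq"
  alns$keep <- is.na(reason)
  alns$drop_reason <- reason
  alns
}

#' Extract SV evidence from alignment CIGARs
#'
#' Walks each CIGAR in reference coordinates: every D or N op becomes a
#' deletion record at the first deleted base, every I op an insertion
#' record anchored at the base before which the sequence is inserted. Ops of
#' every size are emitted; the SV-versus-indel cut is applied later at
#' clustering.
#'
#' @param alns data.frame with query_name, chrom, pos, cigar columns (kept
#'   spliced alignments, contig alignments, or primary BAM records).
#' @param source Evidence source label (RAW_CLIP, EXTENDED, CONTIG,
#'   CIGAR_BAM).
#' @param reads Character vector, parallel to rows of \code{alns}, of
#'   comma-separated constituent read names (defaults to query_name;
#'   extended sequences contribute their two source reads).
#' @return Evidence data.frame: svtype, chrom, pos, size, source,
#'   query_name, reads.
#' @export
call_from_cigar <- function(alns, source = "RAW_CLIP",
                            reads = alns$query_name) {
  empty <- data.frame(svtype = character(0), chrom = character(0),
                      pos = integer(0), size = integer(0),
                      source = character(0), query_name = character(0),
                      reads = character(0), stringsAsFactors = FALSE)
  if (nrow(alns) == 0) return(empty)
  check_that(all(grepl("^([0-9]+[MIDNSHP=X])+$", alns$cigar)),
             "malformed CIGAR")
  del <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alns$cigar, pos = alns$pos, ops = c("D", "N"))
  ins_r <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alns$cigar, pos = alns$pos, ops = "I")
  ins_q <- GenomicAlignments::cigarRangesAlongQuerySpace(
    alns$cigar, ops = "I")
  nd <- S4Vectors::elementNROWS(del)
  ni <- S4Vectors::elementNROWS(ins_r)
  out <- list()
  if (sum(nd)) {
    out$del <- data.frame(
      svtype = "DEL",
      chrom = rep(alns$chrom, nd),
      pos = unlist(IRanges::start(del), use.names = FALSE),
      size = unlist(IRanges::width(del), use.names = FALSE),
      source = source,
      query_name = rep(alns$query_name, nd),
      reads = rep(reads, nd), stringsAsFactors = FALSE)
  }
  if (sum(ni)) {
    out$ins <- data.frame(
      svtype = "INS",
      chrom = rep(alns$chrom, ni),
      pos = unlist(IRanges::start(ins_r), use.names = FALSE),
      size = unlist(IRanges::width(ins_q), use.names = FALSE),
      source = source,
      query_name = rep(alns$query_name, ni),
      reads = rep(reads, ni), stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Cluster SV evidence into calls
#'
#' Evidence records of the same type whose positions lie within
#' \code{pos_tol} bp and whose sizes agree within \code{size_tol}
#' (fraction of the cluster's first size) merge into one call at the median
#' position and median size. Support counts distinct source reads; an
#' extended sequence contributes its two constituent reads. Calls with
#' support below \code{X} are dropped, as are calls smaller than
#' \code{min_size} (those are indels, not SVs) unless \code{min_size} is
#' \code{NA}.
#'
#' @param ev Evidence data.frame (\code{\link{call_from_cigar}}).
#' @param X Support threshold.
#' @param min_size Minimum call size (default 50; \code{NA} keeps all).
#' @param pos_tol,size_tol Merge tolerances.
#' @return Canonical call data.frame (evidence column = predominant
#'   source).
#' @export
cluster_evidence <- function(ev, X, min_size = 50L, pos_tol = 10L,
                             size_tol = 0.2) {
  if (nrow(ev) == 0) return(empty_calls())
  rows <- list()
  for (key in unique(paste(ev$chrom, ev$svtype))) {
    sub <- ev[paste(ev$chrom, ev$svtype) == key, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$size), , drop = FALSE]
    # position-link pass
    grp <- cumsum(c(TRUE, diff(sub$pos) > pos_tol))
    for (g in unique(grp)) {
      block <- sub[grp == g, , drop = FALSE]
      block <- block[order(block$size), , drop = FALSE]
      anchor <- block$size[1]
      sgrp <- integer(nrow(block)); cur <- 1L
      sgrp[1] <- 1L
      for (i in seq_len(nrow(block))[-1]) {
        if (block$size[i] - anchor > size_tol * anchor) {
          cur <- cur + 1L; anchor <- block$size[i]
        }
        sgrp[i] <- cur
      }
      for (s in unique(sgrp)) {
        cl <- block[sgrp == s, , drop = FALSE]
        rd <- unique(unlist(strsplit(cl$reads, ",", fixed = TRUE)))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cl$chrom[1], pos = as.integer(round(median(cl$pos))),
          svtype = cl$svtype[1],
          size = as.integer(round(median(cl$size))),
          support = length(rd),
          evidence = names(sort(table(cl$source), decreasing = TRUE))[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- as_calls(do.call(rbind, rows))
  calls <- calls[calls$support >= X, , drop = FALSE]
  if (!is.na(min_size)) {
    calls <- calls[calls$size >= min_size, , drop = FALSE]
  }
  calls$end <- ifelse(calls$svtype == "DEL" | calls$svtype == "INV",
                      calls$pos + calls$size, calls$pos)
  sort_calls(calls)
}
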