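#' Split a genome into scanning chunks
#'
#' @param ref Path to an indexed reference FASTA, or a named numeric vector
#'   of chromosome lengths.
#' @param width Chunk width in bp (default 1 Mb).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive). The terminal chunk of each chromosome may be
#'   shorter than \code{width}.
#' @export
genome_chunks <- function(ref, width = 1e6) {
  lens <- chrom_lengths(ref)
  out <- lapply(names(lens), function(ch) {
    n <- lens[[ch]]
    starts <- seq(1, n, by = width)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width - 1, n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

chrom_lengths <- function(ref) {
  if (is.character(ref) && length(ref) == 1) {
    fa <- Rsamtools::FaFile(ref)
    if (!file.exists(paste0(ref, ".fai"))) Rsamtools::indexFa(ref)
    si <- GenomeInfoDb::seqinfo(fa)
    setNames(GenomeInfoDb::seqlengths(si), GenomeInfoDb::seqnames(si))
  } else if (methods::is(ref, "DNAStringSet")) {
    setNames(Biostrings::width(ref), names(ref))
  } else {
    check_that(!is.null(names(ref)), "ref lengths must be named")
    ref
  }
}

.bam_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize", "seq", "qual")

#' Read alignments overlapping a genome region
#'
#' Fetches every BAM record overlapping the region and returns a flat
#' data.frame, one row per record, with SAM flags unpacked into logical
#' columns and the SA (supplementary alignment) tag carried along.
#' Duplicate-flagged records are returned tagged (\code{duplicate == TRUE});
#' downstream consumers drop them.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param chrom Chromosome name; unknown names yield an empty frame with a
#'   warning.
#' @param start,end Region (1-based inclusive); defaults cover the
#'   chromosome.
#' @return data.frame with columns qname, flag, chrom, pos, mapq, cigar,
#'   mate_chrom, mate_pos, tlen, seq, qual, sa and unpacked flag logicals.
#' @export
scan_reads <- function(bam, chrom, start = 1L, end = NULL) {
  bf <- Rsamtools::BamFile(bam)
  si <- Rsamtools::scanBamHeader(bf)$targets
  if (!chrom %in% names(si)) {
    warning("chromosome '", chrom, "' not present in BAM header")
    return(empty_reads())
  }
  if (is.null(end)) end <- si[[chrom]]
  end <- min(end, si[[chrom]])
  if (start > end) return(empty_reads())
  param <- Rsamtools::ScanBamParam(
    what = .bam_what, tag = "SA",
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  reads_frame(res)
}

empty_reads <- function() {
  reads_frame(list(qname = character(0), flag = integer(0),
                   rname = factor(), pos = integer(0), mapq = integer(0),
                   cigar = character(0), mrnm = factor(),
                   mpos = integer(0), isize = integer(0),
                   seq = Biostrings::DNAStringSet(),
                   qual = Biostrings::BStringSet(),
                   tag = list(SA = character(0))))
}

reads_frame <- function(res) {
  flag <- as.integer(res$flag)
  df <- data.frame(
    qname = res$qname, flag = flag,
    chrom = as.character(res$rname), pos = as.integer(res$pos),
    mapq = as.integer(res$mapq), cigar = as.character(res$cigar),
    mate_chrom = as.character(res$mrnm), mate_pos = as.integer(res$mpos),
    tlen = as.integer(res$isize),
    seq = as.character(res$seq), qual = as.character(res$qual),
    sa = if (!is.null(res$tag$SA)) as.character(res$tag$SA)
         else rep(NA_character_, length(flag)),
    stringsAsFactors = FALSE
  )
  df$paired        <- flag_bit(flag, 0x1)
  df$proper_pair   <- flag_bit(flag, 0x2)
  df$unmapped      <- flag_bit(flag, 0x4)
  df$mate_unmapped <- flag_bit(flag, 0x8)
  df$reverse       <- flag_bit(flag, 0x10)
  df$mate_reverse  <- flag_bit(flag, 0x20)
  df$first_of_pair <- flag_bit(flag, 0x40)
  df$secondary     <- flag_bit(flag, 0x100)
  df$duplicate     <- flag_bit(flag, 0x400)
  df$supplementary <- flag_bit(flag, 0x800)
  df$primary       <- !df$secondary & !df$supplementary
  df
}

#' Insert-size and coverage statistics for a region
#'
#' Estimates the library insert-size distribution from primary,
#' non-duplicate read pairs with mapping quality exactly 60, counting each
#' pair once through its leftmost mate (TLEN > 0). The standard deviation is
#' the population form so that tiny fixtures are exactly checkable. The read
#' length is the longest aligned (soft-clip-excluded) query length observed;
#' coverage is total aligned reference bases divided by the region width.
#'
#' @param reads data.frame from \code{\link{scan_reads}}.
#' @param region_width Width (bp) of the region the reads came from.
#' @param fallback \code{insert_stats} to reuse when no read qualifies
#'   (e.g. the previous chunk's estimate); \code{NULL} falls back to
#'   conservative defaults with a warning.
#' @return List of class \code{"insert_stats"}: \code{mean}, \code{sd},
#'   \code{read_length}, \code{coverage}.
#' @export
estimate_library_stats <- function(reads, region_width, fallback = NULL) {
  usable <- reads[reads$primary & !reads$duplicate & !reads$unmapped, ,
                  drop = FALSE]
  coverage <- if (nrow(usable)) {
    sum(GenomicAlignments::cigarWidthAlongReferenceSpace(usable$cigar)) /
      region_width
  } else 0
  read_length <- if (nrow(usable)) {
    max(GenomicAlignments::cigarWidthAlongQuerySpace(
      usable$cigar, after.soft.clipping = TRUE))
  } else NA_integer_
  q <- usable[usable$paired & usable$mapq == 60 & !is.na(usable$tlen) &
                usable$tlen > 0, , drop = FALSE]
  if (nrow(q) == 0) {
    warning("no mapq-60 pairs for insert-size estimation; using fallback")
    fb <- if (!is.null(fallback)) fallback else
      insert_stats(mean = 500, sd = 150, read_length = 150, coverage = 1)
    return(insert_stats(fb$mean, fb$sd,
                        if (is.na(read_length)) fb$read_length else read_length,
                        max(coverage, 1e-6)))
  }
  tl <- as.numeric(q$tlen)
  insert_stats(mean = mean(tl),
               sd = sqrt(mean((tl - mean(tl))^2)),
               read_length = read_length,
               coverage = coverage)
}

#' @rdname estimate_library_stats
#' @param mean,sd Insert-size mean and standard deviation (bp).
#' @param read_length Read length (bp).
#' @param coverage Sequencing coverage (x).
#' @export
insert_stats <- function(mean, sd, read_length, coverage) {
  check_that(sd >= 0 && read_length > 0 && coverage > 0,
             "invalid insert statistics")
  structure(list(mean = mean, sd = sd,
                 read_length = as.integer(read_length),
                 coverage = coverage),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf(
    "<insert_stats> mean=%.1f sd=%.1f read_length=%d coverage=%.1fx\n",
    x$mean, x$sd, x$read_length, x$coverage))
  invisible(x)
}

#' High-quality base ratio
#'
#' Fraction of bases with Phred value strictly greater than 20 within a
#' 1-based inclusive interval of a quality vector.
#'
#' @param quals Integer vector of Phred values.
#' @param start,end Interval bounds (1-based inclusive, default the full
#'   vector).
#' @return Fraction in [0, 1].
#' @examples
#' hq_base_ratio(c(30, 30, 10, 30))  # 0.75
#' @export
hq_base_ratio <- function(quals, start = 1L, end = length(quals)) {
  check_that(length(quals) > 0 && start >= 1 && end <= length(quals) &&
               start <= end, "empty or out-of-range interval")
  mean(quals[start:end] > 20)
}
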