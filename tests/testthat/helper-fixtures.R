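# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# One-row read frame matching clipcall's scan_reads() layout, without a BAM.
make_read <- function(qname = "r1", chrom = "chr1", pos = 1000L,
                      mapq = 60L, cigar = "150M", seq = NULL, qual = NULL,
                      mate_chrom = chrom, mate_pos = 2000L, tlen = 400L,
                      sa = NA_character_, paired = TRUE, proper = TRUE,
                      unmapped = FALSE, mate_unmapped = FALSE,
                      reverse = FALSE, mate_reverse = TRUE,
                      secondary = FALSE, duplicate = FALSE,
                      supplementary = FALSE, first = TRUE) {
  qlen <- tryCatch(
    GenomicAlignments::cigarWidthAlongQuerySpace(cigar),
    error = function(e) 150L)
  if (is.null(seq)) seq <- random_dna(qlen)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  flag <- sum(c(0x1, 0x2, 0x4, 0x8, 0x10, 0x20, 0x40, 0x100, 0x400,
                0x800)[c(paired, proper, unmapped, mate_unmapped, reverse,
                         mate_reverse, first, secondary, duplicate,
                         supplementary)])
  data.frame(
    qname = qname, flag = as.integer(flag), chrom = chrom,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
    tlen = as.integer(tlen), seq = seq, qual = qual, sa = sa,
    paired = paired, proper_pair = proper, unmapped = unmapped,
    mate_unmapped = mate_unmapped, reverse = reverse,
    mate_reverse = mate_reverse, first_of_pair = first,
    secondary = secondary, duplicate = duplicate,
    supplementary = supplementary,
    primary = !secondary & !supplementary,
    stringsAsFactors = FALSE
  )
}

make_reads <- function(...) do.call(rbind, list(...))

# Write a FASTA + faidx for a named character vector of chromosomes.
write_test_ref <- function(seqs, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  Rsamtools::indexFa(path)
  path
}

# Build an indexed BAM from SAM body lines (header derived from ref seqs).
write_test_bam <- function(sam_body, ref_lens,
                           dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lens),
                   as.integer(ref_lens)))
  samf <- file.path(dir, "test.sam")
  writeLines(c(hdr, sam_body), samf)
  bam <- Rsamtools::asBam(samf, file.path(dir, "test"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# SAM record line; seq defaults to a run of A of the query length.
sam_line <- function(qname, flag, chrom, pos, mapq, cigar,
                     mate_chrom = "=", mate_pos = 0L, tlen = 0L,
                     seq = NULL, qual = NULL, tags = character(0)) {
  if (is.null(seq)) {
    qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
    seq <- strrep("A", qlen)
  }
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(c(qname, flag, chrom, pos, mapq, cigar, mate_chrom, mate_pos,
          tlen, seq, qual, tags), collapse = "\t")
}

# Independent CIGAR walker used as the oracle for call_from_cigar and
# extract_clips breakpoints: a plain regex walk, no shared code.
oracle_cigar_walk <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  typ <- sub("^[0-9]+", "", ops)
  refpos <- pos
  events <- list()
  for (i in seq_along(typ)) {
    if (typ[i] %in% c("M", "=", "X")) {
      refpos <- refpos + lens[i]
    } else if (typ[i] %in% c("D", "N")) {
      events[[length(events) + 1L]] <- list(type = "DEL", pos = refpos,
                                            size = lens[i])
      refpos <- refpos + lens[i]
    } else if (typ[i] == "I") {
      events[[length(events) + 1L]] <- list(type = "INS", pos = refpos,
                                            size = lens[i])
    }
  }
  list(events = events, ref_end = refpos)
}

# Brute-force maximum bipartite matching (augmenting paths) over a logical
# compatibility matrix; oracle for the greedy matcher.
oracle_max_matching <- function(compat) {
  nc <- nrow(compat); nt <- ncol(compat)
  match_t <- rep(0L, nt)
  try_call <- function(i, seen) {
    for (j in seq_len(nt)) {
      if (compat[i, j] && !seen[j]) {
        seen[j] <- TRUE
        if (match_t[j] == 0L) {
          match_t[j] <<- i
          return(TRUE)
        }
        prev <- match_t[j]
        match_t[j] <<- i
        if (try_call(prev, seen)) return(TRUE)
        match_t[j] <<- prev
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_len(nc)) {
    if (try_call(i, rep(FALSE, nt))) n <- n + 1L
  }
  n
}
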