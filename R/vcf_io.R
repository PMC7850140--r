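#' Write SV calls to a VCF 4.2 file
#'
#' Emits a site-only VCF with symbolic ALT alleles (\code{<DEL>},
#' \code{<INS>}, \code{<INV>}) and paired breakend (BND) records for
#' translocations. \code{POS} is the first affected base (1-based) and
#' \code{END = POS + size}, matching the internal convention that a deletion
#' occupies \code{[pos, pos + size)}. Calls without a resolved size carry
#' the \code{IMPRECISE} flag and omit \code{SVLEN}/\code{END}.
#'
#' @param calls Canonical call data.frame (see \code{\link{run_caller}}),
#'   sorted by chromosome and position.
#' @param reference Path to the reference FASTA (indexed; used for contig
#'   headers and REF bases).
#' @param out Output path.
#' @return \code{out}, invisibly.
#' @export
write_sv_vcf <- function(calls, reference, out) {
  calls <- as_calls(calls)
  lens <- chrom_lengths(reference)
  if (nrow(calls)) {
    ord <- order(match(calls$chrom, names(lens)), calls$pos)
    check_that(identical(ord, seq_len(nrow(calls))),
               "calls must be sorted by (chrom, pos)")
    check_that(all(calls$chrom %in% names(lens)),
               "call chromosome absent from reference")
    check_that(all(calls$pos >= 1 & calls$pos <= lens[calls$chrom]),
               "call position outside reference")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clipcall",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=EVIDENCE,Number=1,Type=String,Description=\"Evidence class\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Breakend mate id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(calls)) {
    fa <- Rsamtools::FaFile(reference)
    gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos,
                                                               calls$pos))
    refb <- as.character(Biostrings::getSeq(fa, gr))
    ids <- ifelse(is.na(calls$id),
                  sprintf("clipcall_%d", seq_len(nrow(calls))), calls$id)
    body <- vapply(seq_len(nrow(calls)), function(i) {
      x <- calls[i, ]
      info <- sprintf("SVTYPE=%s", if (x$svtype == "TRA") "BND" else x$svtype)
      if (x$svtype %in% c("DEL", "INV") && !is.na(x$size)) {
        info <- paste0(info, sprintf(";END=%d", x$pos + x$size))
      }
      if (!is.na(x$size)) {
        slen <- if (x$svtype == "DEL") -x$size else x$size
        info <- paste0(info, sprintf(";SVLEN=%d", slen))
      }
      if (!is.na(x$support)) info <- paste0(info, sprintf(";SUPPORT=%d",
                                                          x$support))
      if (!is.na(x$evidence)) info <- paste0(info, sprintf(";EVIDENCE=%s",
                                                           x$evidence))
      if (isTRUE(x$imprecise)) info <- paste0(info, ";IMPRECISE")
      alt <- switch(x$svtype,
        DEL = "<DEL>", INS = "<INS>", INV = "<INV>",
        TRA = , BND = sprintf("%s[%s:%d[", refb[i], x$partner_chrom,
                              x$partner_pos))
      if (x$svtype %in% c("TRA", "BND") && !is.na(x$mate_id)) {
        info <- paste0(info, sprintf(";MATEID=%s", x$mate_id))
      }
      paste(x$chrom, x$pos, ids[i], refb[i], alt, ".", "PASS", info,
            sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), out)
  invisible(out)
}

#' Read SV calls from a VCF
#'
#' Parses a structural-variant VCF (as written by \code{\link{write_sv_vcf}}
#' or any VCF with SVTYPE/SVLEN/END annotations) back into the canonical
#' call data.frame. Parsing goes through \pkg{VariantAnnotation} so the
#' round trip exercises an independent reader.
#'
#' @param path VCF path.
#' @return Canonical call data.frame.
#' @export
read_sv_vcf <- function(path) {
  check_that(requireNamespace("VariantAnnotation", quietly = TRUE),
             "VariantAnnotation is required to read VCFs")
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0) return(empty_calls())
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  svtype <- unlist(info$SVTYPE)
  svlen <- if ("SVLEN" %in% names(info)) {
    sapply(info$SVLEN, function(e) if (length(e)) as.integer(e[[1]]) else NA_integer_)
  } else rep(NA_integer_, n)
  support <- if ("SUPPORT" %in% names(info)) as.integer(info$SUPPORT)
             else rep(NA_integer_, n)
  evidence <- if ("EVIDENCE" %in% names(info)) as.character(info$EVIDENCE)
              else rep(NA_character_, n)
  imprecise <- if ("IMPRECISE" %in% names(info)) as.logical(info$IMPRECISE)
               else rep(FALSE, n)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  partner_chrom <- rep(NA_character_, n)
  partner_pos <- rep(NA_integer_, n)
  is_bnd <- svtype == "BND"
  if (any(is_bnd)) {
    m <- regmatches(alt[is_bnd],
                    regexec("[][]([^:]+):([0-9]+)[][]", alt[is_bnd]))
    partner_chrom[is_bnd] <- vapply(m, function(x) x[2], character(1))
    partner_pos[is_bnd] <- as.integer(vapply(m, function(x) x[3],
                                             character(1)))
  }
  mate_id <- if ("MATEID" %in% names(info)) {
    sapply(info$MATEID, function(e) if (length(e)) as.character(e[[1]]) else NA_character_)
  } else rep(NA_character_, n)
  svtype[is_bnd] <- "TRA"
  as_calls(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    svtype = svtype,
    size = abs(svlen),
    support = support, evidence = evidence,
    imprecise = imprecise,
    partner_chrom = partner_chrom, partner_pos = partner_pos,
    id = names(rr), mate_id = mate_id,
    stringsAsFactors = FALSE
  ))
}
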