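#' Resolve one insertion candidate through the decision tree
#'
#' Evaluates, in order, four ways an insertion could explain a
#' clipped-read-supported candidate breakpoint, stopping at the first that
#' succeeds:
#' \enumerate{
#'   \item \strong{CIGAR}: I ops of at least \code{min_sv} bp in the
#'     original alignments near the candidate give an exact-size call; an
#'     I/D cluster below \code{min_sv} bp with at least X reads explains
#'     the candidate as a small indel and terminates the tree.
#'   \item \strong{Spliced alignment}: an insertion call from the
#'     read-extension + spliced-alignment pipeline near the candidate.
#'   \item \strong{Local assembly}: de Bruijn contigs over the breakpoint
#'     window, spliced-aligned back, give a fully or partially assembled
#'     insertion.
#'   \item \strong{Complex read alignment}: confidently aligned clipped
#'     reads whose mates are unmapped or on other chromosomes rescue
#'     insertions whose content resists alignment.
#' }
#' Candidates lying within \code{match_window} bp of an already-called
#' deletion, inversion or translocation are explained by that event and
#' yield no insertion (the tree's exclusion rule, applied before the
#' assembly and complex nodes).
#'
#' @param candidate One-row candidate data.frame
#'   (\code{\link{collect_candidate_breakpoints}}).
#' @param ctx Pipeline context: list with \code{reads} (chunk read frame),
#'   \code{clips} (quality-filtered clips), \code{spliced_ins} (insertion
#'   calls from the spliced pipeline), \code{dels}, \code{invs},
#'   \code{tras} (call sets for the exclusion rule), \code{bam},
#'   \code{ref} (FaFile or DNAStringSet), \code{X}.
#' @param config \code{\link{caller_config}}.
#' @return List: \code{status} ("call", "indel" or "none"), \code{node}
#'   (CIGAR, SPLICED, ASSEMBLY_FULL, ASSEMBLY_PARTIAL or COMPLEX) and
#'   \code{call} (one-row canonical call data.frame, for status "call").
#' @export
resolve_insertion <- function(candidate, ctx, config = caller_config()) {
  for (need in c("dels", "invs", "tras")) {
    check_that(!is.null(ctx[[need]]),
               paste0("ctx$", need, " call set is required"))
  }
  w <- config$match_window
  bp <- candidate$pos
  # --- node 1: original-alignment CIGAR ---------------------------------
  n1 <- .node_cigar(candidate, ctx, config)
  if (!is.null(n1)) return(n1)
  # --- node 2: read extension + spliced alignment -----------------------
  si <- ctx$spliced_ins
  if (!is.null(si) && nrow(si)) {
    hit <- si[si$chrom == candidate$chrom & abs(si$pos - bp) <= w, ,
              drop = FALSE]
    if (nrow(hit)) {
      call <- hit[order(abs(hit$pos - bp)), , drop = FALSE][1, , drop = FALSE]
      call$evidence <- "SPLICED"
      call <- .mask_repeat_size(call, candidate, ctx$clips)
      return(list(status = "call", node = "SPLICED", call = as_calls(call)))
    }
  }
  # --- exclusion: candidate explained by another SV type ----------------
  if (.overlaps_callset(candidate, ctx, w)) {
    return(list(status = "none", node = NA_character_, call = NULL))
  }
  # --- node 3: local de Bruijn assembly ---------------------------------
  n3 <- .node_assembly(candidate, ctx, config)
  if (!is.null(n3)) return(n3)
  # --- node 4: complex read alignment -----------------------------------
  call <- complex_alignment_node(candidate, ctx$clips,
                                 list(dels = ctx$dels, invs = ctx$invs,
                                      tras = ctx$tras),
                                 ctx$X, config)
  if (!is.null(call)) {
    return(list(status = "call", node = "COMPLEX", call = call))
  }
  list(status = "none", node = NA_character_, call = NULL)
}

.node_cigar <- function(candidate, ctx, config) {
  reads <- ctx$reads
  w <- config$match_window
  bp <- candidate$pos
  near <- reads[reads$chrom == candidate$chrom & reads$primary &
                  !reads$duplicate & !reads$unmapped &
                  reads$mapq >= config$min_mapq &
                  reads$pos <= bp + w &
                  reads$pos + nchar(reads$seq) >= bp - w, , drop = FALSE]
  if (nrow(near) == 0) return(NULL)
  ev <- call_from_cigar(.as_alignment_table(near), source = "CIGAR_BAM")
  ev <- ev[abs(ev$pos - bp) <= w, , drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  cl <- cluster_evidence(ev, X = ctx$X, min_size = NA)
  if (nrow(cl) == 0) return(NULL)
  big_ins <- cl[cl$svtype == "INS" & cl$size >= config$min_sv, ,
                drop = FALSE]
  if (nrow(big_ins)) {
    call <- big_ins[order(abs(big_ins$pos - bp)), ,
                    drop = FALSE][1, , drop = FALSE]
    call$evidence <- "CIGAR"
    call <- .mask_repeat_size(call, candidate, ctx$clips)
    return(list(status = "call", node = "CIGAR", call = as_calls(call)))
  }
  small <- cl[cl$size < config$min_sv, , drop = FALSE]
  if (nrow(small)) {
    call <- small[order(abs(small$pos - bp)), ,
                  drop = FALSE][1, , drop = FALSE]
    call$evidence <- "CIGAR"
    return(list(status = "indel", node = "CIGAR", call = as_calls(call)))
  }
  NULL
}

# adapt a read frame to the alignment-table columns call_from_cigar expects
.as_alignment_table <- function(reads) {
  data.frame(query_name = reads$qname, chrom = reads$chrom,
             pos = reads$pos, cigar = reads$cigar, stringsAsFactors = FALSE)
}

# Tandem-periodic clipped sequences at a candidate mean the junction
# content is a repeat array: a read-scale alignment cannot count the
# copies, so any insertion size read off a CIGAR there collapses repeat
# units. The call is kept but its size is masked (IMPRECISE).
.mask_repeat_size <- function(call, candidate, clips) {
  if (is.null(clips) || nrow(clips) == 0 || is.na(call$size)) return(call)
  cc <- clips[clips$chrom == candidate$chrom &
                abs(clips$bp - candidate$pos) <= 5L &
                nchar(clips$clipped_seq) >= 25L, , drop = FALSE]
  if (nrow(cc) == 0) return(call)
  periodic <- vapply(cc$clipped_seq, .is_tandem_periodic, logical(1))
  if (mean(periodic) >= 0.5) {
    call$size <- NA_integer_
    call$imprecise <- TRUE
  }
  call
}

# TRUE when the sequence matches itself shifted by some period <= 25 bp
# over at least 90% of the compared positions.
.is_tandem_periodic <- function(s, max_period = 25L, min_ident = 0.9) {
  n <- nchar(s)
  a <- strsplit(s, "")[[1]]
  for (p in 2:max_period) {
    if (n - p < 15L) break
    if (mean(a[1:(n - p)] == a[(p + 1):n]) >= min_ident) return(TRUE)
  }
  FALSE
}

.overlaps_callset <- function(candidate, ctx, w) {
  for (set in list(ctx$dels, ctx$invs, ctx$tras)) {
    if (is.null(set) || nrow(set) == 0) next
    same <- set[set$chrom == candidate$chrom, , drop = FALSE]
    if (nrow(same) == 0) next
    lo <- same$pos - w
    hi <- ifelse(is.na(same$end), same$pos, same$end) + w
    if (any(candidate$pos >= lo & candidate$pos <= hi)) return(TRUE)
  }
  FALSE
}

.node_assembly <- function(candidate, ctx, config) {
  reads <- collect_assembly_reads(ctx$bam, candidate$chrom, candidate$pos,
                                  window = config$assembly_window,
                                  config = config)
  if (nrow(reads) == 0) return(NULL)
  contigs <- assemble_pooled(reads$seq, kmers = config$kmers)
  if (nrow(contigs) == 0) return(NULL)
  win <- 5000L
  lens <- chrom_lengths(ctx$ref)
  lo <- max(1L, candidate$pos - win)
  hi <- min(lens[[candidate$chrom]], candidate$pos + win)
  refseq <- .fetch_ref(ctx$ref, candidate$chrom, lo, hi)
  queries <- setNames(contigs$contig,
                      sprintf("contig_%d_k%d", seq_len(nrow(contigs)),
                              contigs$k))
  alns <- spliced_align(queries, refseq, candidate$chrom, window_start = lo,
                        backend = config$backend)
  alns <- alns[alns$mapq >= 10L, , drop = FALSE]
  call <- call_from_contigs(alns, candidate$chrom, candidate$pos,
                            min_sv = config$min_sv,
                            window = config$match_window)
  if (is.null(call)) return(NULL)
  list(status = "call", node = call$evidence, call = call)
}

.fetch_ref <- function(ref, chrom, lo, hi) {
  if (methods::is(ref, "DNAStringSet")) {
    as.character(Biostrings::subseq(ref[[chrom]], lo, hi))
  } else {
    fa <- if (methods::is(ref, "FaFile")) ref else Rsamtools::FaFile(ref)
    as.character(Biostrings::getSeq(
      fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))))[[1]]
  }
}

#' Complex-read-alignment rescue node
#'
#' Counts clipped reads at the candidate breakpoint that are themselves
#' aligned with high confidence (mapping quality >= 50 and a
#' high-quality-base ratio of the mapped segment >= 0.8) while their mates
#' are unmapped or aligned to another chromosome — the signature of an
#' insertion whose content cannot be placed on the reference. A call
#' requires at least X such reads and no deletion, inversion or
#' translocation call within \code{match_window} bp.
#'
#' @param candidate One-row candidate data.frame.
#' @param clips Quality-filtered clip data.frame.
#' @param exclusion List with \code{dels}, \code{invs}, \code{tras} call
#'   sets.
#' @param X Support threshold.
#' @param config \code{\link{caller_config}}.
#' @return One-row canonical call (size unknown, imprecise), or
#'   \code{NULL}.
#' @export
complex_alignment_node <- function(candidate, clips, exclusion, X,
                                   config = caller_config()) {
  if (.overlaps_callset(candidate,
                        list(dels = exclusion$dels, invs = exclusion$invs,
                             tras = exclusion$tras),
                        config$match_window)) {
    return(NULL)
  }
  cc <- clips[clips$chrom == candidate$chrom &
                abs(clips$bp - candidate$pos) <= 5L, , drop = FALSE]
  qualify <- cc$mapq >= config$complex_mapq &
    !is.na(cc$mapped_hq) & cc$mapped_hq >= config$complex_hq_ratio &
    (cc$mate_unmapped |
       (!is.na(cc$mate_chrom) & cc$mate_chrom != cc$chrom))
  n <- length(unique(cc$qname[qualify]))
  if (n < X) return(NULL)
  as_calls(data.frame(
    chrom = candidate$chrom, pos = candidate$pos, svtype = "INS",
    size = NA_integer_, support = n, evidence = "COMPLEX",
    imprecise = TRUE, stringsAsFactors = FALSE))
}
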