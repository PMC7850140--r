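#' Run the SV caller over a BAM
#'
#' End-to-end chunked pipeline. Per 1 Mb chunk (scanned with a margin so
#' extension bins and candidate windows never straddle a hard boundary):
#' library statistics, signal classification, clipped-read extraction,
#' candidate collection, read extension + spliced alignment (deletions and
#' short insertions), inversion and translocation calling, and the
#' insertion decision tree (which consumes the deletion/inversion/
#' translocation sets for its exclusion rule). Chunk results are merged
#' with boundary duplicates collapsed and the output ordered canonically,
#' so results are independent of the number of worker processes.
#'
#' @param bam Coordinate-sorted, indexed BAM of paired-end short reads.
#' @param ref Reference FASTA path (indexed on the fly if needed).
#' @param out_vcf Optional output VCF path.
#' @param config \code{\link{caller_config}}.
#' @param threads Worker processes for chunk-level parallelism.
#' @return List of class \code{"clipcall_run"}: \code{calls} (canonical
#'   call data.frame), \code{manifest} (config snapshot and per-chunk
#'   tallies), and \code{vcf} (path or NULL).
#' @export
run_caller <- function(bam, ref, out_vcf = NULL, config = caller_config(),
                       threads = 1L) {
  check_that(file.exists(bam), paste("BAM not found:", bam))
  chunks <- genome_chunks(ref, width = config$chunk_width)
  fa_lens <- chrom_lengths(ref)
  worker <- function(i) {
    run_chunk(bam, ref, chunks$chrom[i], chunks$start[i], chunks$end[i],
              fa_lens, config)
  }
  results <- if (threads > 1L) {
    parallel::mclapply(seq_len(nrow(chunks)), worker, mc.cores = threads)
  } else {
    lapply(seq_len(nrow(chunks)), worker)
  }
  calls <- do.call(rbind, lapply(results, `[[`, "calls"))
  calls <- merge_chunk_calls(as_calls(calls), config)
  manifest <- list(
    tool = "clipcall",
    version = as.character(utils::packageVersion("clipcall")),
    config = unclass(config),
    bam = bam, ref = ref,
    chunks = do.call(rbind, lapply(results, `[[`, "tally")),
    n_calls = nrow(calls)
  )
  vcf <- NULL
  if (!is.null(out_vcf)) {
    write_sv_vcf(calls, ref, out_vcf)
    vcf <- out_vcf
  }
  structure(list(calls = calls, manifest = manifest, vcf = vcf),
            class = "clipcall_run")
}

#' @export
print.clipcall_run <- function(x, ...) {
  cat(sprintf("<clipcall_run> %d call(s)\n", nrow(x$calls)))
  if (nrow(x$calls)) print(table(x$calls$svtype))
  invisible(x)
}

# One chunk of the pipeline. Candidate ownership is [start, end]; reads are
# scanned with the configured margin on both sides.
run_chunk <- function(bam, ref, chrom, start, end, fa_lens, config) {
  scan_lo <- max(1L, start - config$chunk_margin)
  scan_hi <- min(fa_lens[[chrom]], end + config$chunk_margin)
  reads <- scan_reads(bam, chrom, scan_lo, scan_hi)
  tally <- data.frame(chrom = chrom, start = start, end = end,
                      n_reads = nrow(reads), n_candidates = 0L,
                      n_del = 0L, n_ins = 0L, n_inv = 0L, n_tra = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    return(list(calls = empty_calls(), tally = tally))
  }
  stats <- suppressWarnings(
    estimate_library_stats(reads, scan_hi - scan_lo + 1L))
  X <- support_threshold(stats$coverage, config$support_frac,
                         config$min_support_floor)
  work <- reads[reads$primary & !reads$duplicate & !reads$unmapped, ,
                drop = FALSE]
  work <- classify_reads(work, stats, config)
  clips <- extract_clips(work, config)
  qclips <- filter_clips(clips, config)
  candidates <- collect_candidate_breakpoints(qclips, X)
  candidates <- candidates[candidates$pos >= start & candidates$pos <= end,
                           , drop = FALSE]
  tally$n_candidates <- nrow(candidates)

  # --- deletions & short insertions: extension + spliced alignment ------
  ext <- extend_clipped_reads(qclips, stats$read_length, config)
  spliced <- .spliced_stage(qclips, ext, ref, chrom, fa_lens, config)
  ev_bam <- call_from_cigar(
    .as_alignment_table(work[work$mapq >= config$min_mapq, , drop = FALSE]),
    source = "CIGAR_BAM")
  del_ev <- rbind(spliced[spliced$svtype == "DEL", , drop = FALSE],
                  ev_bam[ev_bam$svtype == "DEL", , drop = FALSE])
  dels <- cluster_evidence(del_ev, X = X, min_size = config$min_sv,
                           pos_tol = config$cluster_pos_tol,
                           size_tol = config$cluster_size_tol)
  spliced_ins <- cluster_evidence(
    spliced[spliced$svtype == "INS", , drop = FALSE], X = X,
    min_size = config$min_sv, pos_tol = config$cluster_pos_tol,
    size_tol = config$cluster_size_tol)

  # --- inversions and translocations ------------------------------------
  invs <- call_inversions(work, qclips, stats, X, config)
  tras <- call_translocations(work, qclips, X, config)

  # --- insertion decision tree ------------------------------------------
  ctx <- list(reads = work, clips = qclips, spliced_ins = spliced_ins,
              dels = dels, invs = invs, tras = tras, bam = bam, ref = ref,
              X = X)
  ins_rows <- list()
  indel_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    res <- resolve_insertion(candidates[i, , drop = FALSE], ctx, config)
    if (res$status == "call") {
      ins_rows[[length(ins_rows) + 1L]] <- res$call
    } else if (res$status == "indel" && config$emit_indels) {
      indel_rows[[length(indel_rows) + 1L]] <- res$call
    }
  }
  ins <- dedupe_calls(as_calls(do.call(rbind, ins_rows)), config)
  own <- function(x) x[x$pos >= start & x$pos <= end, , drop = FALSE]
  dels <- own(dels); invs <- own(invs)
  tras <- tras[(tras$pos >= start & tras$pos <= end) |
                 tras$chrom != chrom, , drop = FALSE]
  tally$n_del <- nrow(dels); tally$n_ins <- nrow(ins)
  tally$n_inv <- nrow(invs); tally$n_tra <- nrow(tras)
  calls <- rbind(dels, ins, invs, tras,
                 as_calls(do.call(rbind, indel_rows)))
  list(calls = as_calls(calls), tally = tally)
}

# Spliced alignment of raw clipped reads and extended sequences around
# their anchor positions; returns pooled SV evidence.
.spliced_stage <- function(qclips, ext, ref, chrom, fa_lens, config) {
  empty <- call_from_cigar(.empty_alignments())
  usable <- qclips[nzchar(qclips$clipped_seq), , drop = FALSE]
  queries <- data.frame(
    name = character(0), seq = character(0), bp = integer(0),
    reads = character(0), stringsAsFactors = FALSE)
  if (nrow(usable)) {
    raw <- usable[!duplicated(usable$qname), , drop = FALSE]
    queries <- rbind(queries, data.frame(
      name = paste0("raw|", raw$qname), seq = raw$read_seq, bp = raw$bp,
      reads = raw$qname, stringsAsFactors = FALSE))
  }
  if (nrow(ext)) {
    queries <- rbind(queries, data.frame(
      name = ext$name, seq = ext$sequence, bp = ext$bp,
      reads = paste(ext$ms_qname, ext$sm_qname, sep = ","),
      stringsAsFactors = FALSE))
  }
  if (nrow(queries) == 0) return(empty)
  queries <- queries[order(queries$bp), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(queries$bp) > 10000L))
  ev <- list()
  for (g in unique(grp)) {
    q <- queries[grp == g, , drop = FALSE]
    lo <- max(1L, min(q$bp) - config$spliced_window)
    hi <- min(fa_lens[[chrom]], max(q$bp) + config$spliced_window)
    refseq <- .fetch_ref(ref, chrom, lo, hi)
    alns <- spliced_align(setNames(q$seq, q$name), refseq, chrom,
                          window_start = lo, backend = config$backend)
    if (nrow(alns) == 0) next
    alns <- filter_alignments(alns)
    alns <- alns[alns$keep, , drop = FALSE]
    if (nrow(alns) == 0) next
    src <- ifelse(startsWith(alns$query_name, "raw|"), "RAW_CLIP",
                  "EXTENDED")
    rd <- q$reads[match(alns$query_name, q$name)]
    ev[[length(ev) + 1L]] <- call_from_cigar(alns, source = src[1],
                                             reads = rd)
    # per-row sources when mixed
    ev[[length(ev)]]$source <- src[match(ev[[length(ev)]]$query_name,
                                         alns$query_name)]
  }
  if (length(ev) == 0) return(empty)
  do.call(rbind, ev)
}

# Collapse near-identical calls of one type (same type within pos_tol and
# size within size_tol); keeps the higher-support record.
dedupe_calls <- function(calls, config = caller_config()) {
  if (nrow(calls) <= 1) return(calls)
  calls <- sort_calls(calls)
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (calls$svtype[i] != calls$svtype[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (abs(calls$pos[i] - calls$pos[j]) > config$cluster_pos_tol) next
      si <- calls$size[i]; sj <- calls$size[j]
      size_ok <- is.na(si) || is.na(sj) ||
        abs(si - sj) <= config$cluster_size_tol * max(si, sj)
      if (!size_ok) next
      # keep the better-supported of the two
      bi <- ifelse(is.na(calls$support[i]), 0L, calls$support[i])
      bj <- ifelse(is.na(calls$support[j]), 0L, calls$support[j])
      if (bi > bj) keep[j] <- FALSE else keep[i] <- FALSE
      break
    }
  }
  calls[keep, , drop = FALSE]
}

# Merge chunk outputs: dedupe boundary duplicates and reciprocal TRA pairs,
# then renumber breakend ids canonically.
merge_chunk_calls <- function(calls, config) {
  if (nrow(calls) == 0) return(calls)
  tras <- calls[calls$svtype == "TRA", , drop = FALSE]
  rest <- calls[calls$svtype != "TRA", , drop = FALSE]
  rest <- dedupe_calls(rest, config)
  if (nrow(tras)) {
    key <- apply(tras[, c("chrom", "pos", "partner_chrom", "partner_pos")],
                 1, function(r) {
      a <- paste(r["chrom"],
                 round(as.integer(r["pos"]) / 100) * 100)
      b <- paste(r["partner_chrom"],
                 round(as.integer(r["partner_pos"]) / 100) * 100)
      paste(sort(c(a, b)), collapse = "~")
    })
    # rebuild reciprocal records with fresh ids
    rebuilt <- list()
    uk <- unique(key)
    for (i in seq_along(uk)) {
      row <- tras[match(uk[i], key), , drop = FALSE]
      ida <- sprintf("TRA%d_1", i); idb <- sprintf("TRA%d_2", i)
      a <- row; a$id <- ida; a$mate_id <- idb
      b <- row
      b$chrom <- row$partner_chrom; b$pos <- row$partner_pos
      b$partner_chrom <- row$chrom; b$partner_pos <- row$pos
      b$id <- idb; b$mate_id <- ida
      rebuilt[[length(rebuilt) + 1L]] <- rbind(a, b)
    }
    tras <- as_calls(do.call(rbind, rebuilt))
  }
  sort_calls(rbind(rest, tras))
}
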