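#' Collect reads for local assembly around a breakpoint
#'
#' Extracts, within a 1.2 kb window centered on a candidate breakpoint,
#' all clipped reads and improperly paired reads (proper-pair flag 0x2
#' absent) with mapping quality >= 20, together with their mates wherever
#' those map — including unmapped mates stored alongside the pair.
#' Duplicates are excluded. Sequences are returned in original read
#' orientation (reverse-strand alignments are reverse-complemented back).
#'
#' @param bam Indexed BAM path.
#' @param chrom,bp Breakpoint position.
#' @param window Window width in bp (default 1200).
#' @param config \code{\link{caller_config}}.
#' @return data.frame with qname, seq, qual — FASTQ-ready read records
#'   (possibly empty).
#' @export
collect_assembly_reads <- function(bam, chrom, bp, window = 1200L,
                                   config = caller_config()) {
  half <- as.integer(window / 2)
  reads <- scan_reads(bam, chrom, max(1L, bp - half), bp + half)
  reads <- reads[!reads$duplicate & !reads$secondary &
                   !reads$supplementary, , drop = FALSE]
  if (nrow(reads) == 0) return(.empty_fastq())
  cig <- ifelse(is.na(reads$cigar), "", reads$cigar)
  cl <- terminal_clip_lengths(cig)
  clipped <- !reads$unmapped &
    pmax(cl$lead, cl$trail) > config$min_clip
  improper <- reads$paired & !reads$proper_pair
  sel <- (clipped | improper) & !reads$unmapped &
    reads$mapq >= config$min_mapq
  picked <- reads[sel, , drop = FALSE]
  if (nrow(picked) == 0) return(.empty_fastq())
  # placed-unmapped mates of selected reads already fall in the window scan
  local_mates <- reads[reads$qname %in% picked$qname &
                         !(paste(reads$qname, reads$flag) %in%
                             paste(picked$qname, picked$flag)), ,
                       drop = FALSE]
  # mates mapped elsewhere: fetch their regions
  need <- picked[!picked$mate_unmapped & !is.na(picked$mate_chrom) &
                   !(paste(picked$qname, picked$mate_pos) %in%
                       paste(local_mates$qname, local_mates$pos)), ,
                 drop = FALSE]
  far_mates <- .empty_fastq_reads()
  if (nrow(need)) {
    regs <- unique(data.frame(chrom = need$mate_chrom, pos = need$mate_pos,
                              stringsAsFactors = FALSE))
    got <- lapply(seq_len(nrow(regs)), function(i) {
      scan_reads(bam, regs$chrom[i], max(1L, regs$pos[i] - 1L),
                 regs$pos[i] + 1L)
    })
    got <- do.call(rbind, got)
    far_mates <- got[got$qname %in% need$qname & got$primary &
                       !got$duplicate &
                       got$first_of_pair != picked$first_of_pair[
                         match(got$qname, picked$qname)], , drop = FALSE]
  }
  all_reads <- unique(rbind(picked, local_mates, far_mates))
  seqs <- all_reads$seq
  quals <- all_reads$qual
  flip <- all_reads$reverse & !all_reads$unmapped
  if (any(flip)) {
    seqs[flip] <- revcomp(seqs[flip])
    quals[flip] <- vapply(quals[flip], function(q) {
      paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1))
  }
  mate_tag <- ifelse(all_reads$first_of_pair, "/1", "/2")
  df <- data.frame(qname = paste0(all_reads$qname, mate_tag), seq = seqs,
                   qual = quals, stringsAsFactors = FALSE)
  df <- df[!duplicated(df$qname), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_fastq <- function() {
  data.frame(qname = character(0), seq = character(0), qual = character(0),
             stringsAsFactors = FALSE)
}

.empty_fastq_reads <- function() empty_reads()

#' Local de Bruijn assembly
#'
#' Builds the k-mer de Bruijn graph over the reads and their reverse
#' complements (nodes are k-mers, edges are observed (k+1)-mers), prunes
#' nodes seen fewer than \code{min_count} times, compresses non-branching
#' paths into unitigs, clips tips shorter than \code{2k}, pops simple
#' bubbles keeping the higher-coverage arm, and reports the remaining
#' unitigs as contigs.
#'
#' @param seqs Character vector of read sequences.
#' @param k Odd k-mer size, smaller than the shortest read used.
#' @param min_count k-mer count cutoff (default 2: a single read never
#'   yields a contig).
#' @return data.frame: contig, k, mean_cov. Empty when nothing survives
#'   pruning.
#' @export
debruijn_assemble <- function(seqs, k, min_count = 2L) {
  empty <- data.frame(contig = character(0), k = integer(0),
                      mean_cov = numeric(0), stringsAsFactors = FALSE)
  seqs <- seqs[!is.na(seqs) & nchar(seqs) > k]
  if (length(seqs) == 0) return(empty)
  both <- c(seqs, revcomp(seqs))
  km <- unlist(lapply(both, kmerize, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(empty)
  cnt <- table(km)
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0) return(empty)
  nodes <- names(cnt)
  counts <- as.integer(cnt)
  ek <- unlist(lapply(both, kmerize, k = k + 1L), use.names = FALSE)
  ek <- unique(ek[!grepl("[^ACGT]", ek)])
  from <- match(substr(ek, 1L, k), nodes)
  to <- match(substr(ek, 2L, k + 1L), nodes)
  oke <- !is.na(from) & !is.na(to)
  g <- list(nodes = nodes, counts = counts,
            from = from[oke], to = to[oke])
  for (round in 1:3) {
    uni <- .dbg_unitigs(g, k)
    if (nrow(uni$unitigs) == 0) return(empty)
    pruned <- .dbg_prune(uni, k)
    if (!pruned$changed) {
      uni <- pruned$uni
      break
    }
    g <- .dbg_subset(g, pruned$keep_nodes)
    uni <- pruned$uni
  }
  out <- uni$unitigs[nchar(uni$unitigs$seq) >= k, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  data.frame(contig = out$seq, k = k, mean_cov = out$cov,
             stringsAsFactors = FALSE)
}

# Compress maximal non-branching paths. Returns the unitig table plus the
# unitig-level adjacency needed for tip/bubble pruning.
.dbg_unitigs <- function(g, k) {
  n <- length(g$nodes)
  outdeg <- tabulate(g$from, n)
  indeg <- tabulate(g$to, n)
  succ <- vector("list", n)
  ord <- order(g$from)
  if (length(g$from)) {
    succ_split <- split(g$to[ord], g$from[ord])
    succ[as.integer(names(succ_split))] <- succ_split
  }
  pred <- vector("list", n)
  ordp <- order(g$to)
  if (length(g$to)) {
    pred_split <- split(g$from[ordp], g$to[ordp])
    pred[as.integer(names(pred_split))] <- pred_split
  }
  is_start <- indeg != 1L |
    vapply(seq_len(n), function(i) {
      p <- pred[[i]]
      length(p) == 1L && outdeg[p] > 1L
    }, logical(1))
  visited <- logical(n)
  utigs <- list()
  walk <- function(start) {
    path <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      if (outdeg[cur] != 1L) break
      nxt <- succ[[cur]][1]
      if (indeg[nxt] != 1L || visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <<- TRUE
      cur <- nxt
    }
    path
  }
  for (i in which(is_start)) {
    if (visited[i]) next
    utigs[[length(utigs) + 1L]] <- walk(i)
  }
  for (i in seq_len(n)) { # leftover cycles
    if (!visited[i]) utigs[[length(utigs) + 1L]] <- walk(i)
  }
  seqs <- vapply(utigs, function(path) {
    paste0(g$nodes[path[1]],
           paste(substr(g$nodes[path[-1]], k, k), collapse = ""))
  }, character(1))
  cov <- vapply(utigs, function(path) mean(g$counts[path]), numeric(1))
  first <- vapply(utigs, function(p) p[1], integer(1))
  last <- vapply(utigs, function(p) p[length(p)], integer(1))
  list(
    unitigs = data.frame(seq = seqs, cov = cov, first = first, last = last,
                         stringsAsFactors = FALSE),
    members = utigs, succ = succ, pred = pred,
    indeg = indeg, outdeg = outdeg, g = g
  )
}

# One pruning pass: drop short tips and pop simple bubbles. Returns the
# surviving node set and whether anything changed.
.dbg_prune <- function(uni, k) {
  u <- uni$unitigs
  drop <- logical(nrow(u))
  len <- nchar(u$seq)
  # tips: dangling at one end, attached to a branch at the other, short
  for (i in seq_len(nrow(u))) {
    dang_in <- uni$indeg[u$first[i]] == 0L
    dang_out <- uni$outdeg[u$last[i]] == 0L
    attached <- (!dang_in && uni$outdeg[u$first[i]] >= 1L) ||
      (!dang_out && uni$indeg[u$last[i]] >= 1L)
    if ((dang_in != dang_out) && len[i] < 2L * k &&
        nrow(u) > 1L && attached) {
      drop[i] <- TRUE
    }
  }
  # simple bubbles: two unitigs whose first nodes share the predecessor set
  # and whose last nodes share the successor set
  if (nrow(u) > 1) {
    keyf <- vapply(seq_len(nrow(u)), function(i) {
      paste(sort(uni$pred[[u$first[i]]]), collapse = ",")
    }, character(1))
    keyl <- vapply(seq_len(nrow(u)), function(i) {
      paste(sort(uni$succ[[u$last[i]]]), collapse = ",")
    }, character(1))
    key <- paste(keyf, keyl, sep = "|")
    for (kk in unique(key[duplicated(key)])) {
      idx <- which(key == kk & !drop & nzchar(gsub("\\|", "", kk)))
      if (length(idx) < 2) next
      sim <- abs(len[idx] - max(len[idx])) <= 0.1 * max(len[idx])
      idx <- idx[sim]
      if (length(idx) < 2) next
      keep_arm <- idx[order(-u$cov[idx], u$seq[idx])][1]
      drop[setdiff(idx, keep_arm)] <- TRUE
    }
  }
  if (!any(drop)) {
    return(list(changed = FALSE, uni = uni))
  }
  gone <- unlist(uni$members[drop], use.names = FALSE)
  keep_nodes <- setdiff(seq_along(uni$g$nodes), gone)
  list(changed = TRUE, keep_nodes = keep_nodes, uni = uni)
}

.dbg_subset <- function(g, keep_nodes) {
  remap <- rep(NA_integer_, length(g$nodes))
  remap[keep_nodes] <- seq_along(keep_nodes)
  oke <- !is.na(remap[g$from]) & !is.na(remap[g$to])
  list(nodes = g$nodes[keep_nodes], counts = g$counts[keep_nodes],
       from = remap[g$from[oke]], to = remap[g$to[oke]])
}

#' Assemble a breakpoint window at multiple k
#'
#' Runs \code{\link{debruijn_assemble}} for each k (default 41, 61, 81) and
#' pools the contigs without deduplication; downstream clustering absorbs
#' redundancy.
#'
#' @param seqs Read sequences.
#' @param kmers Integer vector of k values.
#' @return Pooled contig data.frame.
#' @export
assemble_pooled <- function(seqs, kmers = c(41L, 61L, 81L)) {
  out <- lapply(kmers, function(k) debruijn_assemble(seqs, k))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Call an insertion from contig alignments
#'
#' Two insertion classes: a fully assembled insertion shows as an I op of at
#' least \code{min_sv} bp in a contig CIGAR within \code{window} bp of the
#' breakpoint (exact size, inserted sequence recoverable); a partially
#' assembled insertion shows as a contig soft-clipped by more than
#' \code{min_sv} bp with the clip boundary within \code{window} bp of the
#' breakpoint (size unknown, imprecise). A full call is preferred whenever
#' both exist.
#'
#' @param alns Contig alignments (\code{\link{spliced_align}} output).
#' @param chrom,bp Breakpoint.
#' @param min_sv Minimum insertion size (default 50).
#' @param window Breakpoint tolerance in bp (default 200).
#' @return One-row canonical call data.frame (evidence ASSEMBLY_FULL or
#'   ASSEMBLY_PARTIAL), or \code{NULL}.
#' @export
call_from_contigs <- function(alns, chrom, bp, min_sv = 50L,
                              window = 200L) {
  if (nrow(alns) == 0) return(NULL)
  ev <- call_from_cigar(alns, source = "CONTIG")
  full <- ev[ev$svtype == "INS" & ev$size >= min_sv &
               abs(ev$pos - bp) <= window, , drop = FALSE]
  if (nrow(full)) {
    cl <- cluster_evidence(full, X = 1L, min_size = min_sv)
    cl <- cl[order(abs(cl$pos - bp)), , drop = FALSE]
    call <- cl[1, , drop = FALSE]
    call$evidence <- "ASSEMBLY_FULL"
    call$imprecise <- FALSE
    return(call)
  }
  cl <- terminal_clip_lengths(alns$cigar)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(alns$cigar)
  lead_bp <- alns$pos
  trail_bp <- alns$pos + refw
  partial <- (cl$lead > min_sv & abs(lead_bp - bp) <= window) |
    (cl$trail > min_sv & abs(trail_bp - bp) <= window)
  if (any(partial)) {
    bps <- ifelse(cl$lead > min_sv & abs(lead_bp - bp) <= window,
                  lead_bp, trail_bp)[partial]
    return(as_calls(data.frame(
      chrom = chrom, pos = as.integer(round(median(bps))), svtype = "INS",
      size = NA_integer_, support = sum(partial),
      evidence = "ASSEMBLY_PARTIAL", imprecise = TRUE,
      stringsAsFactors = FALSE)))
  }
  NULL
}
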