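#' Simulate a toy reference genome
#'
#' Uniform-random DNA with optional planted tandem-repeat arrays (20-mer
#' units), mimicking the repeat-enriched neighbourhoods in which real SVs
#' concentrate. Repeat arrays give the aligner and assembler realistically
#' awkward flanks.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param n_repeats Tandem arrays planted per chromosome (each ~300 bp: a
#'   20-mer repeated 15 times).
#' @param seed Optional RNG seed.
#' @return \code{DNAStringSet} named chr1..chrN.
#' @export
simulate_reference <- function(n_chrom = 1L, chrom_len = 1e6,
                               n_repeats = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
    if (n_repeats > 0) {
      for (r in seq_len(n_repeats)) {
        unit <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                      collapse = "")
        arr <- strrep(unit, 15L)
        at <- sample.int(chrom_len - nchar(arr) - 1L, 1L)
        substr(s, at, at + nchar(arr) - 1L) <- arr
      }
    }
    s
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_chrom))))
}

#' Random SV genotypes
#'
#' Draws genotypes i.i.d. uniformly over "1|1" (homozygous), "0|1" and
#' "1|0" (phased heterozygous), so the expected homozygous:heterozygous
#' ratio is 1:2.
#'
#' @param n Number of events.
#' @param seed Optional RNG seed.
#' @return Character vector of genotypes.
#' @export
assign_genotypes <- function(n, seed = NULL) {
  check_that(n >= 1, "n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sample(c("1|1", "0|1", "1|0"), n, replace = TRUE)
}

#' Generate random deletion/insertion/inversion events
#'
#' Events are placed uniformly at random, rejecting positions within
#' \code{min_gap} bp of a previously placed event, and sized uniformly in
#' the given ranges. A fraction of the insertion sequences are tandem
#' 20-mer arrays to mimic the repetitive content of real insertions.
#'
#' @param ref Reference \code{DNAStringSet}.
#' @param n_del,n_ins,n_inv Event counts.
#' @param del_size,ins_size,inv_size Size ranges (bp); the inversion
#'   default spans 50 bp to 10 kb.
#' @param repeat_frac Fraction of insertions with tandem-repeat content.
#' @param min_gap Minimum distance (bp) between events.
#' @param existing Event table whose positions (plus \code{min_gap}) the
#'   new events must avoid.
#' @param seed Optional RNG seed.
#' @return Event data.frame: svtype, chrom, pos, size, seq (INS only),
#'   sorted by (chrom, pos).
#' @export
simulate_sv_events <- function(ref, n_del = 0L, n_ins = 0L, n_inv = 0L,
                               del_size = c(100L, 5000L),
                               ins_size = c(60L, 800L),
                               inv_size = c(50L, 10000L),
                               repeat_frac = 0.3, min_gap = 1000L,
                               existing = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- setNames(Biostrings::width(ref), names(ref))
  placed <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(existing) && nrow(existing)) {
    span <- ifelse(existing$svtype == "INS", 1L,
                   ifelse(is.na(existing$size), 1L, existing$size))
    placed <- data.frame(chrom = existing$chrom, start = existing$pos,
                         end = existing$pos + span,
                         stringsAsFactors = FALSE)
  }
  types <- c(rep("DEL", n_del), rep("INS", n_ins), rep("INV", n_inv))
  if (length(types) == 0) {
    return(data.frame(svtype = character(0), chrom = character(0),
                      pos = integer(0), size = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (tp in types) {
    rng <- switch(tp, DEL = del_size, INS = ins_size, INV = inv_size)
    size <- sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
    ok <- FALSE
    for (try in 1:500) {
      chrom <- sample(names(lens), 1L, prob = lens)
      span <- if (tp == "INS") 1L else size
      if (lens[[chrom]] < span + 2L * min_gap + 2L) next
      pos <- sample.int(lens[[chrom]] - span - 2L * min_gap, 1L) + min_gap
      lo <- pos - min_gap; hi <- pos + span + min_gap
      conflict <- any(placed$chrom == chrom & placed$start <= hi &
                        placed$end >= lo)
      if (!conflict) { ok <- TRUE; break }
    }
    check_that(ok, "could not place event; genome too small or too full")
    placed <- rbind(placed, data.frame(chrom = chrom, start = pos,
                                       end = pos + span,
                                       stringsAsFactors = FALSE))
    seq <- NA_character_
    if (tp == "INS") {
      if (runif(1) < repeat_frac && size >= 40L) {
        unit <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                      collapse = "")
        seq <- substr(strrep(unit, ceiling(size / 20L)), 1L, size)
      } else {
        seq <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = "")
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      svtype = tp, chrom = chrom, pos = as.integer(pos),
      size = as.integer(size), seq = seq, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$chrom, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Simulate random inversion events
#'
#' Convenience wrapper around \code{\link{simulate_sv_events}} matching the
#' benchmark design: 200 inversions, 50 bp to 10 kb, placed at least 1 kb
#' from any existing event.
#'
#' @param ref Reference \code{DNAStringSet}.
#' @param events Existing event table to respect and extend (or
#'   \code{NULL}).
#' @param n Number of inversions (default 200).
#' @param len_range Size range in bp.
#' @param min_gap Minimum distance to other events.
#' @param seed Optional RNG seed.
#' @return Combined, sorted event data.frame.
#' @export
simulate_inversions <- function(ref, events = NULL, n = 200L,
                                len_range = c(50L, 10000L),
                                min_gap = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(events)
  inv <- simulate_sv_events(ref, n_inv = n, inv_size = len_range,
                            min_gap = min_gap, existing = events)
  out <- rbind(events, inv)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike SV events into a reference to build a diploid genome
#'
#' Applies each event to haplotype 1, haplotype 2 or both according to its
#' genotype. Events are applied right-to-left within each chromosome so
#' earlier reference positions stay valid. A deletion removes
#' \code{[pos, pos + size)}; an insertion places its sequence before
#' \code{pos}; an inversion reverse-complements \code{[pos, pos + size)}.
#' The truth table records events in reference coordinates.
#'
#' @param ref Reference \code{DNAStringSet}.
#' @param events Event data.frame (\code{\link{simulate_sv_events}}),
#'   sorted, pairwise at least 1 kb apart.
#' @param genotypes Character vector from \code{\link{assign_genotypes}}.
#' @return List of class \code{"diploid_genome"}: \code{ref}, \code{hap1},
#'   \code{hap2} (DNAStringSets) and \code{truth} (events + genotype).
#' @export
spike_svs <- function(ref, events, genotypes) {
  check_that(nrow(events) == length(genotypes),
             "one genotype per event required")
  if (nrow(events)) {
    ord <- order(events$chrom, events$pos)
    check_that(identical(ord, seq_len(nrow(events))),
               "events must be sorted by (chrom, pos)")
    lens <- setNames(Biostrings::width(ref), names(ref))
    span <- ifelse(events$svtype == "INS", 1L, events$size)
    check_that(all(events$pos >= 1 &
                     events$pos + span - 1L <= lens[events$chrom]),
               "event beyond chromosome end")
    by_chr <- split(seq_len(nrow(events)), events$chrom)
    for (idx in by_chr) {
      if (length(idx) > 1) {
        gap <- events$pos[idx[-1]] -
          (events$pos[idx[-length(idx)]] + span[idx[-length(idx)]])
        check_that(all(gap >= 1000L), "events closer than 1 kb")
      }
    }
  }
  hap1 <- as.character(ref)
  hap2 <- as.character(ref)
  truth <- cbind(events, genotype = genotypes, stringsAsFactors = FALSE)
  if (nrow(events)) {
    for (i in rev(seq_len(nrow(events)))) {
      e <- events[i, ]
      gt <- genotypes[i]
      on1 <- gt %in% c("1|1", "1|0")
      on2 <- gt %in% c("1|1", "0|1")
      if (on1) hap1[e$chrom] <- .apply_event(hap1[e$chrom], e)
      if (on2) hap2[e$chrom] <- .apply_event(hap2[e$chrom], e)
    }
  }
  structure(list(ref = ref,
                 hap1 = Biostrings::DNAStringSet(hap1),
                 hap2 = Biostrings::DNAStringSet(hap2),
                 truth = truth),
            class = "diploid_genome")
}

.apply_event <- function(s, e) {
  switch(e$svtype,
    DEL = paste0(substr(s, 1L, e$pos - 1L),
                 substr(s, e$pos + e$size, nchar(s))),
    INS = paste0(substr(s, 1L, e$pos - 1L), e$seq,
                 substr(s, e$pos, nchar(s))),
    INV = paste0(substr(s, 1L, e$pos - 1L),
                 revcomp(substr(s, e$pos, e$pos + e$size - 1L)),
                 substr(s, e$pos + e$size, nchar(s))),
    stop("unsupported event type: ", e$svtype)
  )
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf(
    "<diploid_genome> %d chromosome(s), %d truth event(s)\n",
    length(x$ref), nrow(x$truth)))
  invisible(x)
}

#' Simulate reciprocal translocations
#'
#' For each haplotype, \code{pairs_per_hap} disjoint chromosome pairs are
#' drawn; along each pair, \code{events_per_pair} reciprocal exchanges are
#' applied at ascending cut points (segments alternate between the two
#' derived chromosomes). Every exchange creates one junction on each
#' derived chromosome, i.e. two truth breakpoints, so the defaults yield
#' 60 breakpoints per haplotype. Translocations are heterozygous by
#' construction (each affects one haplotype). Cut points are drawn in
#' reference coordinates at least 1 kb from chromosome ends and previously
#' spiked events, then mapped through the haplotype's indels.
#'
#' @param genome \code{diploid_genome} from \code{\link{spike_svs}}.
#' @param pairs_per_hap Chromosome pairs per haplotype (default 10;
#'   requires at least \code{2 * pairs_per_hap} chromosomes).
#' @param events_per_pair Reciprocal exchanges per pair (default 3).
#' @param min_gap Minimum distance (bp) between cut points and other
#'   events.
#' @param seed Optional RNG seed.
#' @return Updated \code{diploid_genome}; truth gains TRA rows (one per
#'   breakpoint) with partner coordinates and a \code{hap} column.
#' @export
simulate_translocations <- function(genome, pairs_per_hap = 10L,
                                    events_per_pair = 3L, min_gap = 1000L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(genome$ref)
  check_that(length(chroms) >= 2L * pairs_per_hap,
             sprintf("need at least %d chromosomes for %d pairs",
                     2L * pairs_per_hap, pairs_per_hap))
  tra_rows <- list()
  for (hap in 1:2) {
    hap_name <- paste0("hap", hap)
    picked <- sample(chroms, 2L * pairs_per_hap)
    pairs <- matrix(picked, ncol = 2L)
    for (p in seq_len(pairs_per_hap)) {
      ca <- pairs[p, 1]; cb <- pairs[p, 2]
      cuts_a <- .draw_cuts(genome, ca, events_per_pair, min_gap)
      cuts_b <- .draw_cuts(genome, cb, events_per_pair, min_gap)
      sa <- as.character(genome[[hap_name]][ca])
      sb <- as.character(genome[[hap_name]][cb])
      ha <- .map_to_hap(genome$truth, ca, hap, cuts_a)
      hb <- .map_to_hap(genome$truth, cb, hap, cuts_b)
      swapped <- .alternate_segments(sa, sb, ha, hb)
      hs <- as.character(genome[[hap_name]])
      hs[ca] <- swapped$a
      hs[cb] <- swapped$b
      genome[[hap_name]] <- Biostrings::DNAStringSet(hs)
      gt <- if (hap == 1) "1|0" else "0|1"
      for (ei in seq_len(events_per_pair)) {
        tra_rows[[length(tra_rows) + 1L]] <- data.frame(
          svtype = "TRA", chrom = ca, pos = cuts_a[ei], size = NA_integer_,
          seq = NA_character_, genotype = gt, partner_chrom = cb,
          partner_pos = cuts_b[ei], hap = hap, stringsAsFactors = FALSE)
        tra_rows[[length(tra_rows) + 1L]] <- data.frame(
          svtype = "TRA", chrom = cb, pos = cuts_b[ei], size = NA_integer_,
          seq = NA_character_, genotype = gt, partner_chrom = ca,
          partner_pos = cuts_a[ei], hap = hap, stringsAsFactors = FALSE)
      }
    }
  }
  tra <- do.call(rbind, tra_rows)
  truth <- genome$truth
  if (!"partner_chrom" %in% names(truth) && nrow(truth)) {
    truth$partner_chrom <- NA_character_
    truth$partner_pos <- NA_integer_
    truth$hap <- NA_integer_
  }
  genome$truth <- if (nrow(truth)) rbind(truth, tra) else tra
  genome
}

# Ascending cut points >= min_gap apart, clear of chromosome ends and of
# previously placed events on this chromosome.
.draw_cuts <- function(genome, chrom, n, min_gap) {
  len <- Biostrings::width(genome$ref)[match(chrom, names(genome$ref))]
  ev <- genome$truth[genome$truth$chrom == chrom, , drop = FALSE]
  for (try in 1:500) {
    cuts <- sort(sample.int(len - 2L * min_gap, n) + min_gap)
    if (n > 1 && any(diff(cuts) < min_gap)) next
    bad <- FALSE
    if (nrow(ev)) {
      span <- ifelse(ev$svtype == "INS", 1L, ev$size)
      for (cut in cuts) {
        if (any(cut >= ev$pos - min_gap & cut <= ev$pos + span + min_gap)) {
          bad <- TRUE
          break
        }
      }
    }
    if (!bad) return(cuts)
  }
  stop("could not place translocation cuts; use longer chromosomes",
       call. = FALSE)
}

# Map reference coordinates through the haplotype's spiked indels.
.map_to_hap <- function(truth, chrom, hap, pos) {
  if (nrow(truth) == 0) return(pos)
  on_hap <- if (hap == 1) truth$genotype %in% c("1|1", "1|0")
            else truth$genotype %in% c("1|1", "0|1")
  ev <- truth[truth$chrom == chrom & on_hap &
                truth$svtype %in% c("DEL", "INS"), , drop = FALSE]
  vapply(pos, function(p) {
    before <- ev[ev$pos < p, , drop = FALSE]
    delta <- sum(ifelse(before$svtype == "INS", before$size,
                        -before$size))
    as.integer(p + delta)
  }, integer(1))
}

# Reciprocal exchanges at ascending cuts: derived A takes A/B segments
# alternately, derived B the complement.
.alternate_segments <- function(sa, sb, cuts_a, cuts_b) {
  bounds_a <- c(0L, cuts_a, nchar(sa))
  bounds_b <- c(0L, cuts_b, nchar(sb))
  seg_a <- substring(sa, bounds_a[-length(bounds_a)] + 1L,
                     bounds_a[-1])
  seg_b <- substring(sb, bounds_b[-length(bounds_b)] + 1L,
                     bounds_b[-1])
  take_a <- seq_along(seg_a) %% 2L == 1L
  list(a = paste(ifelse(take_a, seg_a, seg_b), collapse = ""),
       b = paste(ifelse(take_a, seg_b, seg_a), collapse = ""))
}

#' Simulate paired-end reads from a diploid genome
#'
#' Draws fragments per haplotype with insert sizes
#' \code{Normal(insert_mean, insert_sd)} (truncated at the read length) at
#' uniform positions, emitting mate 1 from the fragment start and mate 2
#' reverse-complemented from the fragment end; fragments originate from
#' either strand with equal probability. Per-base substitution errors occur
#' with probability \code{error_rate}; erroneous bases receive low Phred
#' values (2-15), correct bases high ones (30-40). Both haplotypes are
#' pooled, giving \code{coverage} total depth.
#'
#' @param genome \code{diploid_genome}.
#' @param coverage Total coverage across both haplotypes (default 30).
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution rate (default 0.002).
#' @param insert_mean,insert_sd Insert-size distribution (bp).
#' @param out_prefix Path prefix; writes \code{<prefix>_1.fq} and
#'   \code{<prefix>_2.fq}.
#' @param seed Optional RNG seed.
#' @return List: fastq1, fastq2, n_pairs.
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 150L,
                           error_rate = 0.002, insert_mean = 500L,
                           insert_sd = 50L, out_prefix = tempfile("sim"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_that(read_len < insert_mean, "read_len must be below insert_mean")
  f1 <- paste0(out_prefix, "_1.fq")
  f2 <- paste0(out_prefix, "_2.fq")
  con1 <- file(f1, "w"); con2 <- file(f2, "w")
  on.exit({ close(con1); close(con2) }, add = TRUE)
  total_pairs <- 0L
  for (hap in c("hap1", "hap2")) {
    seqs <- as.character(genome[[hap]])
    lens <- nchar(seqs)
    n_pairs <- ceiling((coverage / 2) * sum(lens) / (2 * read_len))
    chrom_idx <- sample.int(length(seqs), n_pairs, replace = TRUE,
                            prob = lens)
    ins <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- pmin(ins, lens[chrom_idx])
    start <- floor(runif(n_pairs) * (lens[chrom_idx] - ins)) + 1L
    m1 <- substring(seqs[chrom_idx], start, start + read_len - 1L)
    m2 <- revcomp(substring(seqs[chrom_idx], start + ins - read_len,
                            start + ins - 1L))
    minus <- runif(n_pairs) < 0.5
    r1 <- ifelse(minus, m2, m1)
    r2 <- ifelse(minus, m1, m2)
    q1 <- strrep(sapply(sample(30:40, n_pairs, replace = TRUE) + 33L,
                        function(x) rawToChar(as.raw(x))), read_len)
    q2 <- strrep(sapply(sample(30:40, n_pairs, replace = TRUE) + 33L,
                        function(x) rawToChar(as.raw(x))), read_len)
    if (error_rate > 0) {
      err <- .apply_errors(r1, q1, error_rate)
      r1 <- err$seq; q1 <- err$qual
      err <- .apply_errors(r2, q2, error_rate)
      r2 <- err$seq; q2 <- err$qual
    }
    ids <- sprintf("%s_p%d", hap, seq_len(n_pairs))
    writeLines(as.vector(rbind(paste0("@", ids, "/1"), r1, "+", q1)), con1)
    writeLines(as.vector(rbind(paste0("@", ids, "/2"), r2, "+", q2)), con2)
    total_pairs <- total_pairs + n_pairs
  }
  list(fastq1 = f1, fastq2 = f2, n_pairs = total_pairs)
}

# Sparse per-base substitution errors with matching low quality values.
.apply_errors <- function(seqs, quals, rate) {
  n <- length(seqs)
  if (n == 0) return(list(seq = seqs, qual = quals))
  rl <- nchar(seqs[1])
  total <- n * rl
  m <- stats::rbinom(1L, total, rate)
  if (m == 0) return(list(seq = seqs, qual = quals))
  at <- sample.int(total, m)
  ri <- (at - 1L) %/% rl + 1L
  pi <- (at - 1L) %% rl + 1L
  subs <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  lowq <- vapply(sample(2:15, m, replace = TRUE) + 33L,
                 function(x) rawToChar(as.raw(x)), character(1))
  for (j in seq_len(m)) {
    old <- substr(seqs[ri[j]], pi[j], pi[j])
    new <- subs[j]
    if (new == old) new <- c(A = "C", C = "G", G = "T", T = "A",
                             N = "A")[[old]]
    substr(seqs[ri[j]], pi[j], pi[j]) <- new
    substr(quals[ri[j]], pi[j], pi[j]) <- lowq[j]
  }
  list(seq = seqs, qual = quals)
}

#' Align simulated reads with bwa mem
#'
#' Thin wrapper over the \code{bwa} and \code{samtools} binaries producing
#' a coordinate-sorted, indexed BAM — the input format the caller consumes.
#'
#' @param ref_fa Reference FASTA path (indexed on the fly if needed).
#' @param fq1,fq2 Paired FASTQ paths.
#' @param out_bam Output BAM path.
#' @param threads bwa threads.
#' @return \code{out_bam}, invisibly.
#' @export
align_reads <- function(ref_fa, fq1, fq2, out_bam, threads = 1L) {
  check_that(Sys.which("bwa") != "" && Sys.which("samtools") != "",
             "bwa and samtools binaries are required on PATH")
  if (!file.exists(paste0(ref_fa, ".bwt"))) {
    status <- system2("bwa", c("index", ref_fa), stdout = FALSE,
                      stderr = FALSE)
    check_that(status == 0, "bwa index failed")
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2("bwa", c("mem", "-t", threads, ref_fa, fq1, fq2),
                    stdout = sam, stderr = FALSE)
  check_that(status == 0, "bwa mem failed")
  status <- system2("samtools", c("sort", "-o", out_bam, sam),
                    stdout = FALSE, stderr = FALSE)
  check_that(status == 0, "samtools sort failed")
  status <- system2("samtools", c("index", out_bam), stdout = FALSE,
                    stderr = FALSE)
  check_that(status == 0, "samtools index failed")
  invisible(out_bam)
}

#' Truth table to canonical calls
#'
#' Converts a simulator truth table into the canonical call layout used by
#' the evaluator (one row per event; TRA rows stay one per breakpoint).
#'
#' @param truth Truth data.frame from a \code{diploid_genome}.
#' @return Canonical call data.frame.
#' @export
truth_calls <- function(truth) {
  if (nrow(truth) == 0) return(empty_calls())
  df <- data.frame(
    chrom = truth$chrom, pos = truth$pos, svtype = truth$svtype,
    size = truth$size,
    inserted_seq = if ("seq" %in% names(truth)) truth$seq
                   else NA_character_,
    stringsAsFactors = FALSE)
  if ("partner_chrom" %in% names(truth)) {
    df$partner_chrom <- truth$partner_chrom
    df$partner_pos <- truth$partner_pos
  }
  calls <- as_calls(df)
  calls$end <- ifelse(calls$svtype %in% c("DEL", "INV"),
                      calls$pos + calls$size, calls$pos)
  sort_calls(calls)
}
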