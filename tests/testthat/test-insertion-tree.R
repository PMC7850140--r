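cand <- function(pos = 5000L, support = 5L) {
  data.frame(chrom = "chr1", pos = pos, support = support, n_ms = 3L,
              n_sm = 2L, stringsAsFactors = FALSE)
}

# ctx whose BAM path explodes if the assembly node ever runs
base_ctx <- function(reads = make_read()[0, ], clips = NULL,
                     spliced_ins = empty_calls(), dels = empty_calls(),
                     invs = empty_calls(), tras = empty_calls()) {
  if (is.null(clips)) clips <- extract_clips(make_read(cigar = "150M"))
  list(reads = reads, clips = clips, spliced_ins = spliced_ins,
       dels = dels, invs = invs, tras = tras,
       bam = "/nonexistent/assembly-should-not-run.bam",
       ref = Biostrings::DNAStringSet(c(chr1 = random_dna(100))),
       X = 3L)
}

test_that("a small-indel cluster terminates the tree at the CIGAR node", {
  reads <- do.call(rbind, lapply(1:4, function(i) {
    make_read(qname = paste0("r", i), pos = 4941L, cigar = "60M35I55M")
  }))
  res <- resolve_insertion(cand(), base_ctx(reads = reads))
  expect_equal(res$status, "indel")
  expect_equal(res$node, "CIGAR")
  expect_equal(res$call$size, 35L)
  # nodes 2-4 never ran: the poisoned BAM path was never touched
})

test_that("a >= 50 bp insertion in read CIGARs is called at node 1", {
  reads <- do.call(rbind, lapply(1:4, function(i) {
    make_read(qname = paste0("r", i), pos = 4941L, cigar = "60M60I30M")
  }))
  res <- resolve_insertion(cand(), base_ctx(reads = reads))
  expect_equal(res$status, "call")
  expect_equal(res$node, "CIGAR")
  expect_equal(res$call$svtype, "INS")
  expect_equal(res$call$size, 60L)
  expect_equal(res$call$support, 4L)
})

test_that("a spliced-pipeline insertion resolves at node 2", {
  si <- as_calls(data.frame(chrom = "chr1", pos = 5080L, svtype = "INS",
                            size = 80L, support = 6L,
                            stringsAsFactors = FALSE))
  res <- resolve_insertion(cand(), base_ctx(spliced_ins = si))
  expect_equal(res$status, "call")
  expect_equal(res$node, "SPLICED")
  expect_equal(res$call$size, 80L)
})

test_that("candidates explained by a deletion produce no insertion", {
  dels <- as_calls(data.frame(chrom = "chr1", pos = 5100L, svtype = "DEL",
                              size = 400L, end = 5500L, support = 8L,
                              stringsAsFactors = FALSE))
  res <- resolve_insertion(cand(), base_ctx(dels = dels))
  expect_equal(res$status, "none")
  # the poisoned assembly BAM was never opened: exclusion fired first
})

test_that("the context must carry all three exclusion call sets", {
  ctx <- base_ctx()
  ctx$tras <- NULL
  expect_error(resolve_insertion(cand(), ctx), "tras")
})

complex_clips <- function(n, mapq = 60L, hq = 1, mate_chrom = "chr2",
                          mate_unmapped = FALSE) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(qname = paste0("cx", i), chrom = "chr1", side = "MS",
               bp = 5000L + (i %% 3L), clip_len = 40L,
               clipped_seq = random_dna(40), read_seq = random_dna(150),
               mapq = mapq, mapped_hq = hq, clipped_hq = 0.5,
               supplementary = FALSE, mate_unmapped = mate_unmapped,
               mate_chrom = mate_chrom, stringsAsFactors = FALSE)
  }))
}

test_that("complex-alignment rescue needs confident clips with lost mates", {
  excl <- list(dels = empty_calls(), invs = empty_calls(),
               tras = empty_calls())
  call <- complex_alignment_node(cand(), complex_clips(4), excl, X = 3L)
  expect_equal(call$evidence, "COMPLEX")
  expect_equal(call$support, 4L)
  expect_true(is.na(call$size))
  expect_true(call$imprecise)

  # mapping quality below 50 does not count
  expect_null(complex_alignment_node(cand(), complex_clips(4, mapq = 40L),
                                     excl, X = 3L))
  # low-quality mapped bases do not count
  expect_null(complex_alignment_node(cand(), complex_clips(4, hq = 0.5),
                                     excl, X = 3L))
  # mates on the same chromosome are not complex evidence
  expect_null(complex_alignment_node(
    cand(), complex_clips(4, mate_chrom = "chr1"), excl, X = 3L))
  # unmapped mates qualify
  expect_equal(complex_alignment_node(
    cand(), complex_clips(3, mate_chrom = "chr1", mate_unmapped = TRUE),
    excl, X = 3L)$support, 3L)

  # a translocation 50 bp away vetoes the call
  tra <- as_calls(data.frame(chrom = "chr1", pos = 5050L, svtype = "TRA",
                             support = 9L, partner_chrom = "chr2",
                             partner_pos = 100L, stringsAsFactors = FALSE))
  expect_null(complex_alignment_node(
    cand(), complex_clips(4),
    list(dels = empty_calls(), invs = empty_calls(), tras = tra), X = 3L))
})

test_that("assembly node resolves a planted insertion through a real BAM", {
  dir <- withr::local_tempdir()
  set.seed(30)
  refseq <- random_dna(12000)
  ins_seq <- random_dna(250)
  hap <- paste0(substr(refseq, 1, 6000), ins_seq,
                substr(refseq, 6001, 12000))
  starts <- seq(5200, 6700, by = 6)
  reads1 <- substring(hap, starts, starts + 99)
  # mates placed 300 bp downstream, reverse strand
  reads2 <- revcomp_chr(substring(hap, starts + 200, starts + 299))
  fq1 <- file.path(dir, "r1.fq"); fq2 <- file.path(dir, "r2.fq")
  writeLines(as.vector(rbind(sprintf("@p%d/1", seq_along(starts)), reads1,
                             "+", strrep("I", 100))), fq1)
  writeLines(as.vector(rbind(sprintf("@p%d/2", seq_along(starts)), reads2,
                             "+", strrep("I", 100))), fq2)
  ref_fa <- write_test_ref(c(chr1 = refseq), dir)
  bam <- file.path(dir, "ins.bam")
  align_reads(ref_fa, fq1, fq2, bam)
  ctx <- list(reads = make_read()[0, ],
              clips = extract_clips(make_read(cigar = "150M")),
              spliced_ins = empty_calls(), dels = empty_calls(),
              invs = empty_calls(), tras = empty_calls(),
              bam = bam, ref = Biostrings::DNAStringSet(c(chr1 = refseq)),
              X = 3L)
  res <- resolve_insertion(cand(pos = 6001L), ctx)
  expect_equal(res$status, "call")
  expect_equal(res$node, "ASSEMBLY_FULL")
  expect_equal(res$call$size, 250L)
  expect_lte(abs(res$call$pos - 6001L), 10L)
})
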