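test_that("genome chunking covers chromosomes with a short terminal chunk", {
  ch <- genome_chunks(c(chr1 = 2500000, chr2 = 400000), width = 1e6)
  expect_equal(nrow(ch), 4)
  expect_equal(ch$start[ch$chrom == "chr1"], c(1, 1000001, 2000001))
  expect_equal(ch$end[ch$chrom == "chr1"], c(1000000, 2000000, 2500000))
  expect_true(all(ch$end - ch$start + 1 <= 1e6))
  expect_equal(ch$end[ch$chrom == "chr2"], 400000)
})

test_that("scan_reads returns every overlapping record with flags unpacked", {
  lens <- c(chr1 = 5000L)
  body <- c(
    sam_line("a", 99, "chr1", 100, 60, "100M", "=", 500, 500),
    sam_line("a", 147, "chr1", 500, 60, "100M", "=", 100, -500),
    sam_line("dup", 1123, "chr1", 300, 60, "100M", "=", 700, 500),
    sam_line("clip", 0, "chr1", 1000, 40, "60M40S")
  )
  bam <- write_test_bam(body, lens)
  reads <- scan_reads(bam, "chr1")
  expect_equal(nrow(reads), 4)
  expect_true(reads$duplicate[reads$qname == "dup"])
  expect_false(any(reads$duplicate[reads$qname != "dup"]))
  expect_true(all(reads$proper_pair[reads$qname == "a"]))
  # region query
  expect_equal(nrow(scan_reads(bam, "chr1", 1, 150)), 1)
  # beyond chromosome end
  expect_equal(nrow(scan_reads(bam, "chr1", 4900, 5000)), 0)
  # unknown chromosome
  expect_warning(empty <- scan_reads(bam, "chrX"), "not present")
  expect_equal(nrow(empty), 0)
})

test_that("insert-size statistics use mapq-60 leftmost mates, population sd", {
  r <- make_reads(
    make_read("a", tlen = 400L, mapq = 60L),
    make_read("b", tlen = 400L, mapq = 60L),
    make_read("c", tlen = 400L, mapq = 60L)
  )
  s <- estimate_library_stats(r, region_width = 1e4)
  expect_equal(s$mean, 400)
  expect_equal(s$sd, 0)

  # only mapq-60 reads counted
  r2 <- make_reads(
    make_read("a", tlen = 300L, mapq = 60L),
    make_read("b", tlen = 500L, mapq = 60L),
    make_read("c", tlen = 9000L, mapq = 30L)
  )
  s2 <- estimate_library_stats(r2, region_width = 1e4)
  expect_equal(s2$mean, 400)
  expect_equal(s2$sd, 100) # population sd of {300, 500}

  # negative-TLEN mates are not double counted
  r3 <- rbind(r2, make_read("a2", tlen = -300L, mapq = 60L))
  expect_equal(estimate_library_stats(r3, 1e4)$mean, 400)

  # permutation invariance
  perm <- r2[c(3, 1, 2), ]
  s3 <- estimate_library_stats(perm, 1e4)
  expect_equal(s3$mean, s2$mean)
  expect_equal(s3$sd, s2$sd)

  # fallback with a warning when nothing qualifies
  r4 <- make_read("x", mapq = 20L)
  expect_warning(s4 <- estimate_library_stats(r4, 1e4), "fallback")
  expect_s3_class(s4, "insert_stats")
})

test_that("read length and coverage come from aligned lengths", {
  r <- make_reads(
    make_read("a", cigar = "100M"),
    make_read("b", cigar = "120M30S"),
    make_read("c", cigar = "10S140M")
  )
  s <- estimate_library_stats(r, region_width = 360)
  expect_equal(s$read_length, 140L) # longest aligned (clip-excluded) length
  expect_equal(s$coverage, (100 + 120 + 140) / 360)
})

test_that("high-quality base ratio uses a strict Phred > 20 cut", {
  expect_equal(hq_base_ratio(c(30, 30, 10, 30)), 0.75)
  expect_equal(hq_base_ratio(rep(21, 10)), 1)
  expect_equal(hq_base_ratio(rep(20, 10)), 0)
  expect_equal(hq_base_ratio(c(30, 30, 5, 5), 3, 4), 0)
  expect_equal(hq_base_ratio(c(5, 5, 30, 30), 3, 4), 1)
  expect_error(hq_base_ratio(integer(0)), "empty")
  expect_error(hq_base_ratio(c(30, 30), 2, 1), "interval")
})

test_that("VCF output carries positions, END/SVLEN and flags as specified", {
  dir <- withr::local_tempdir()
  ref <- write_test_ref(c(chr1 = random_dna(3000)), dir)
  calls <- as_calls(data.frame(
    chrom = "chr1", pos = 1000L, svtype = "DEL", size = 500L,
    support = 7L, evidence = "RAW_CLIP", imprecise = FALSE,
    stringsAsFactors = FALSE))
  out <- file.path(dir, "out.vcf")
  write_sv_vcf(calls, ref, out)
  txt <- readLines(out)
  rec <- txt[!startsWith(txt, "#")]
  expect_length(rec, 1)
  f <- strsplit(rec, "\t")[[1]]
  expect_equal(f[2], "1000")
  expect_match(f[8], "END=1500")
  expect_match(f[8], "SVLEN=-500")

  # imprecise insertion: no SVLEN, IMPRECISE flag present
  ins <- as_calls(data.frame(
    chrom = "chr1", pos = 1200L, svtype = "INS", size = NA_integer_,
    support = 4L, evidence = "COMPLEX", imprecise = TRUE,
    stringsAsFactors = FALSE))
  write_sv_vcf(ins, ref, out)
  rec <- readLines(out)
  rec <- rec[!startsWith(rec, "#")]
  expect_match(rec, "IMPRECISE")
  expect_false(grepl("SVLEN", rec))

  # empty call set -> header only
  write_sv_vcf(empty_calls(), ref, out)
  expect_true(all(startsWith(readLines(out), "#")))

  # unsorted input is an error
  two <- rbind(calls, calls)
  two$pos[2] <- 10L
  expect_error(write_sv_vcf(two, ref, out), "sorted")
  bad <- calls
  bad$pos <- 99999L
  expect_error(write_sv_vcf(bad, ref, out), "outside")
})

test_that("VCF round trip preserves chrom/pos/type/size for every call", {
  dir <- withr::local_tempdir()
  ref <- write_test_ref(c(chr1 = random_dna(5000),
                          chr2 = random_dna(5000)), dir)
  calls <- as_calls(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(500L, 2000L, 700L, 701L),
    svtype = c("DEL", "INS", "INV", "TRA"),
    size = c(300L, 75L, 1200L, NA),
    support = c(5L, 4L, 6L, 8L),
    evidence = c("RAW_CLIP", "SPLICED", "INV_READS", "TRA_READS"),
    imprecise = FALSE,
    partner_chrom = c(NA, NA, NA, "chr1"),
    partner_pos = c(NA, NA, NA, 2500L),
    id = c(NA, NA, NA, "TRA1_1"), mate_id = c(NA, NA, NA, "TRA1_2"),
    stringsAsFactors = FALSE))
  out <- file.path(dir, "rt.vcf")
  write_sv_vcf(calls, ref, out)
  back <- read_sv_vcf(out)
  expect_equal(back$chrom, calls$chrom)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$svtype, calls$svtype)
  expect_equal(back$size, calls$size)
  expect_equal(back$support, calls$support)
  expect_equal(back$partner_chrom[4], "chr1")
  expect_equal(back$partner_pos[4], 2500L)
})
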