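# Independent re-application of truth events: walks the reference left to
# right, emitting modified segments — no shared code with spike_svs.
oracle_apply <- function(refseq, events) {
  out <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    out <- c(out, substr(refseq, cursor, e$pos - 1L))
    if (e$svtype == "DEL") {
      cursor <- e$pos + e$size
    } else if (e$svtype == "INS") {
      out <- c(out, e$seq)
      cursor <- e$pos
    } else if (e$svtype == "INV") {
      out <- c(out, revcomp_chr(substr(refseq, e$pos, e$pos + e$size - 1L)))
      cursor <- e$pos + e$size
    }
  }
  paste(c(out, substr(refseq, cursor, nchar(refseq))), collapse = "")
}

test_that("spiking applies events per genotype with exact bookkeeping", {
  set.seed(50)
  ref <- Biostrings::DNAStringSet(c(chr1 = random_dna(100000)))
  ev <- data.frame(svtype = "DEL", chrom = "chr1", pos = 50001L,
                   size = 500L, seq = NA_character_,
                   stringsAsFactors = FALSE)
  gen <- spike_svs(ref, ev, "1|1")
  expect_equal(Biostrings::width(gen$hap1), 99500L)
  expect_equal(Biostrings::width(gen$hap2), 99500L)
  expect_equal(nrow(gen$truth), 1)

  ins <- data.frame(svtype = "INS", chrom = "chr1", pos = 30001L,
                    size = 200L, seq = random_dna(200),
                    stringsAsFactors = FALSE)
  gen2 <- spike_svs(ref, ins, "0|1")
  expect_equal(Biostrings::width(gen2$hap1), 100000L) # hap1 untouched
  expect_equal(Biostrings::width(gen2$hap2), 100200L)

  inv <- data.frame(svtype = "INV", chrom = "chr1", pos = 20001L,
                    size = 1000L, seq = NA_character_,
                    stringsAsFactors = FALSE)
  gen3 <- spike_svs(ref, inv, "1|0")
  seg <- substr(as.character(gen3$hap1), 20001, 21000)
  expect_equal(seg, revcomp_chr(substr(as.character(ref), 20001, 21000)))
  expect_equal(Biostrings::width(gen3$hap1), 100000L)
})

test_that("invalid event tables are rejected", {
  ref <- Biostrings::DNAStringSet(c(chr1 = random_dna(10000)))
  beyond <- data.frame(svtype = "DEL", chrom = "chr1", pos = 9900L,
                       size = 500L, seq = NA_character_,
                       stringsAsFactors = FALSE)
  expect_error(spike_svs(ref, beyond, "1|1"), "beyond")
  close_pair <- data.frame(svtype = "DEL", chrom = "chr1",
                           pos = c(2000L, 2600L), size = c(100L, 100L),
                           seq = NA_character_, stringsAsFactors = FALSE)
  expect_error(spike_svs(ref, close_pair, c("1|1", "1|1")), "1 kb")
  unsorted <- close_pair[2:1, ]
  unsorted$pos <- c(8000L, 2000L)
  expect_error(spike_svs(ref, unsorted, c("1|1", "1|1")), "sorted")
})

test_that("independently re-applying the truth reproduces each haplotype", {
  set.seed(51)
  ref <- simulate_reference(2, 60000, seed = 51)
  ev <- simulate_sv_events(ref, n_del = 4, n_ins = 4, n_inv = 2, seed = 52)
  gt <- assign_genotypes(nrow(ev), seed = 53)
  gen <- spike_svs(ref, ev, gt)
  for (hap in 1:2) {
    gtcol <- if (hap == 1) c("1|1", "1|0") else c("1|1", "0|1")
    for (ch in names(ref)) {
      keep <- gen$truth$chrom == ch & gen$truth$genotype %in% gtcol
      want <- oracle_apply(as.character(ref[[ch]]),
                           gen$truth[keep, , drop = FALSE])
      got <- as.character(gen[[paste0("hap", hap)]][[ch]])
      expect_identical(got, want)
    }
  }
})

test_that("genotypes are uniform over the three phased states and seeded", {
  g <- assign_genotypes(300, seed = 60)
  expect_true(all(g %in% c("1|1", "0|1", "1|0")))
  expect_identical(g, assign_genotypes(300, seed = 60))
  expect_false(identical(g, assign_genotypes(300, seed = 61)))
  # each state appears with roughly probability 1/3
  tab <- table(assign_genotypes(6000, seed = 62))
  expect_true(all(abs(tab / 6000 - 1 / 3) < 0.05))
})

test_that("translocation defaults give 60 breakpoints per haplotype", {
  ref <- simulate_reference(20, 50000, seed = 70)
  gen <- spike_svs(ref, simulate_sv_events(ref), character(0))
  gen <- simulate_translocations(gen, seed = 71)
  tra <- gen$truth[gen$truth$svtype == "TRA", ]
  expect_equal(sum(tra$hap == 1), 60)
  expect_equal(sum(tra$hap == 2), 60)
  expect_equal(nrow(tra), 120)
  expect_true(all(tra$genotype %in% c("1|0", "0|1"))) # always heterozygous
  # sequence is exchanged, never gained or lost
  expect_equal(sum(Biostrings::width(gen$hap1)),
               sum(Biostrings::width(ref)))
  expect_equal(sum(Biostrings::width(gen$hap2)),
               sum(Biostrings::width(ref)))
  # reciprocal partners reference each other
  expect_true(all(tra$partner_chrom != tra$chrom))

  # determinism
  gen_b <- spike_svs(ref, simulate_sv_events(ref), character(0))
  gen_b <- simulate_translocations(gen_b, seed = 71)
  expect_identical(as.character(gen$hap1), as.character(gen_b$hap1))

  # too few chromosomes
  small <- spike_svs(simulate_reference(4, 50000, seed = 72),
                     simulate_sv_events(ref), character(0))
  expect_error(simulate_translocations(small), "at least 20")
})

test_that("read simulation respects coverage, purity and determinism", {
  dir <- withr::local_tempdir()
  ref <- simulate_reference(1, 100000, seed = 80)
  gen <- spike_svs(ref, simulate_sv_events(ref), character(0))
  rd <- simulate_reads(gen, coverage = 30, read_len = 150, error_rate = 0,
                       seed = 81, out_prefix = file.path(dir, "a"))
  l1 <- readLines(rd$fastq1)
  l2 <- readLines(rd$fastq2)
  total_bases <- (length(l1) / 4 + length(l2) / 4) * 150
  expect_lt(abs(total_bases - 30 * 100000) / (30 * 100000), 0.05)

  # with no errors every read is an exact (possibly reverse-complemented)
  # substring of its haplotype
  hap <- as.character(gen$hap1[[1]])
  seqs <- l1[seq(2, length(l1), by = 4)][1:25]
  hits <- vapply(seqs, function(s) {
    grepl(s, hap, fixed = TRUE) || grepl(revcomp_chr(s), hap, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))

  # byte-identical regeneration under the same seed
  rd2 <- simulate_reads(gen, coverage = 30, read_len = 150,
                        error_rate = 0, seed = 81,
                        out_prefix = file.path(dir, "b"))
  expect_identical(readLines(rd2$fastq1), l1)

  # errors appear at roughly the requested rate, with low quality values
  rd3 <- simulate_reads(gen, coverage = 4, read_len = 150,
                        error_rate = 0.01, seed = 82,
                        out_prefix = file.path(dir, "c"))
  l3 <- readLines(rd3$fastq1)
  quals <- paste(l3[seq(4, length(l3), by = 4)], collapse = "")
  frac_low <- mean(as.integer(charToRaw(quals)) - 33L < 20L)
  expect_gt(frac_low, 0.003)
  expect_lt(frac_low, 0.03)
})
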