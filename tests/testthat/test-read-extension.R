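# Brute-force reference implementation of the overlap search: try every n
# from the largest down, literal substring comparison with the boundary
# discount, first success wins.
oracle_join <- function(sm_seq, ms_seq, read_length, min_n = 30L,
                        shift = 3L) {
  la <- nchar(sm_seq); lb <- nchar(ms_seq)
  for (n in seq.int(min(read_length - min_n, la, lb), 1L)) {
    if (n <= min_n) return(NULL)
    for (s in 0:shift) {
      if (n - 2 * s < 1) break
      a <- substr(sm_seq, 1 + s, n - s)
      b <- substr(ms_seq, lb - n + 1 + s, lb - s)
      if (a == b) {
        return(list(n = n, sequence = paste0(ms_seq,
                                             substr(sm_seq, n + 1, la))))
      }
    }
  }
  NULL
}

test_that("a planted head-to-tail overlap joins at the planted n", {
  set.seed(1)
  P <- random_dna(10); O <- random_dna(35); Q <- random_dna(10)
  j <- join_pair(sm_seq = paste0(O, Q), ms_seq = paste0(P, O),
                 read_length = 80L)
  expect_equal(j$n, 35L)
  expect_equal(j$sequence, paste0(P, O, Q))
  expect_equal(nchar(j$sequence), 45L + 45L - 35L)
})

test_that("an overlap of exactly 30 bases is rejected (strict n > 30)", {
  set.seed(2)
  P <- random_dna(15); O <- random_dna(30); Q <- random_dna(15)
  expect_null(join_pair(paste0(O, Q), paste0(P, O), read_length = 80L))
  # one base more succeeds
  O31 <- random_dna(31)
  j <- join_pair(paste0(O31, Q), paste0(P, O31), read_length = 80L)
  expect_equal(j$n, 31L)
})

test_that("up to three boundary bases may mismatch", {
  set.seed(3)
  P <- random_dna(20); O <- random_dna(40); Q <- random_dna(20)
  flip <- function(x) chartr("ACGT", "TGCA", x)
  sm <- paste0(O, Q)
  substr(sm, 1, 1) <- flip(substr(sm, 1, 1)) # error at the clip boundary
  j <- join_pair(sm, paste0(P, O), read_length = 90L)
  expect_equal(j$n, 40L)
  expect_equal(j$shift_used, 1L)
  # a mismatch deep inside the overlap kills the join
  sm2 <- paste0(O, Q)
  substr(sm2, 20, 20) <- flip(substr(sm2, 20, 20))
  expect_null(join_pair(sm2, paste0(P, O), read_length = 90L))
})

test_that("largest-n-first equals the brute-force oracle on random pairs", {
  set.seed(4)
  for (i in 1:40) {
    rl <- sample(c(80L, 100L, 150L), 1)
    if (runif(1) < 0.7) {
      # related pair with a planted overlap
      ov <- sample(25:(rl - 31), 1)
      core <- random_dna(ov)
      sm <- paste0(core, random_dna(rl - ov))
      ms <- paste0(random_dna(rl - ov), core)
    } else {
      sm <- random_dna(rl); ms <- random_dna(rl)
    }
    got <- join_pair(sm, ms, rl)
    want <- oracle_join(sm, ms, rl)
    expect_equal(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_equal(got$n, want$n)
      expect_equal(got$sequence, want$sequence)
      expect_equal(nchar(got$sequence),
                   nchar(ms) + nchar(sm) - got$n)
    }
  }
})

make_clip_pair <- function(ms_bp, sm_bp, ms_seq, sm_seq, ms_name = "ms",
                           sm_name = "sm", chrom = "chr1") {
  rbind(
    data.frame(qname = ms_name, chrom = chrom, side = "MS", bp = ms_bp,
               clip_len = 40L, clipped_seq = substr(ms_seq, 61, 100),
               read_seq = ms_seq, mapq = 60L, mapped_hq = 1,
               clipped_hq = 1, supplementary = FALSE,
               mate_unmapped = FALSE, mate_chrom = chrom,
               stringsAsFactors = FALSE),
    data.frame(qname = sm_name, chrom = chrom, side = "SM", bp = sm_bp,
               clip_len = 40L, clipped_seq = substr(sm_seq, 1, 40),
               read_seq = sm_seq, mapq = 60L, mapped_hq = 1,
               clipped_hq = 1, supplementary = FALSE,
               mate_unmapped = FALSE, mate_chrom = chrom,
               stringsAsFactors = FALSE)
  )
}

test_that("extension pairs clips within 1 kb and skips hard clips", {
  set.seed(5)
  core <- random_dna(50)
  ms_seq <- paste0(random_dna(50), core)
  sm_seq <- paste0(core, random_dna(50))
  near <- make_clip_pair(4500L, 5000L, ms_seq, sm_seq)
  ext <- extend_clipped_reads(near, read_length = 100L)
  expect_equal(nrow(ext), 1)
  expect_equal(ext$n, 50L)
  expect_match(ext$name, "^ms\\|sm\\|n=50$")

  far <- make_clip_pair(6200L, 5000L, ms_seq, sm_seq)
  expect_equal(nrow(extend_clipped_reads(far, read_length = 100L)), 0)

  hard <- near
  hard$clipped_seq[hard$side == "SM"] <- "" # hard clip: no sequence
  expect_equal(nrow(extend_clipped_reads(hard, read_length = 100L)), 0)
})

test_that("each SM read takes its largest-n partner and output is order-invariant", {
  set.seed(6)
  core40 <- random_dna(40)
  sm_seq <- paste0(core40, random_dna(60))
  ms_a <- paste0(random_dna(60), core40)            # overlap 40
  ms_b <- paste0(random_dna(65), substr(core40, 1, 35)) # overlap 35
  clips <- rbind(
    make_clip_pair(5000L, 5050L, ms_a, sm_seq, ms_name = "msA"),
    make_clip_pair(5020L, 5050L, ms_b, sm_seq, ms_name = "msB")
  )
  clips <- clips[clips$qname != "sm" | !duplicated(clips$qname), ]
  ext <- extend_clipped_reads(clips, read_length = 100L)
  expect_equal(nrow(ext), 1)
  expect_equal(ext$n, 40L)
  expect_equal(ext$ms_qname, "msA")
  for (perm in list(sample(nrow(clips)), rev(seq_len(nrow(clips))))) {
    ext2 <- extend_clipped_reads(clips[perm, ], read_length = 100L)
    expect_equal(ext2$name, ext$name)
    expect_equal(ext2$sequence, ext$sequence)
  }
})

test_that("error-free reads across a deletion junction reconstruct the donor", {
  # haplotype with a 150 bp deletion; reads tile the junction
  set.seed(7)
  ref <- random_dna(1000)
  hap <- paste0(substr(ref, 1, 400), substr(ref, 551, 1000))
  # MS read ends 60 into the junction, SM read starts 60 before it
  ms_seq <- substr(hap, 301, 460)  # 100 aligned + 60 past junction
  sm_seq <- substr(hap, 341, 500)  # 60 before junction + 100 after
  clips <- make_clip_pair(401L, 401L, ms_seq, sm_seq)
  ext <- extend_clipped_reads(clips, read_length = 160L)
  expect_equal(nrow(ext), 1)
  # the extension is an exact substring of the donor haplotype with >= 60 bp
  # on each side of the junction
  expect_true(grepl(ext$sequence, hap, fixed = TRUE))
  # ms covers haplotype 301-460, sm 341-500: the join spans 301-500 with
  # 100 bp on each side of the junction at 401
  expect_equal(nchar(ext$sequence), 200L)
  expect_equal(ext$sequence, substr(hap, 301, 500))
})
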