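test_that("builtin aligner recovers planted gaps and inserts exactly", {
  set.seed(10)
  ref <- random_dna(8000)
  # 60 bp flanks of a 500 bp reference gap
  q_del <- paste0(substr(ref, 2001, 2060), substr(ref, 2561, 2620))
  a <- spliced_align(c(q = q_del), ref, "chr1", 1L)
  expect_equal(nrow(a), 1)
  expect_equal(a$pos, 2001L)
  expect_equal(a$cigar, "60M500D60M")
  expect_false(a$boundary_clipped)
  expect_equal(a$boundary_aligned_len, 60L)

  # 35 bp novel insert between adjacent flanks
  q_ins <- paste0(substr(ref, 2001, 2060), random_dna(35),
                  substr(ref, 2061, 2120))
  a2 <- spliced_align(c(q = q_ins), ref, "chr1", 1L)
  expect_equal(a2$cigar, "60M35I60M")
  expect_equal(a2$pos, 2001L)

  # identity: a reference substring aligns gap-free
  a3 <- spliced_align(c(q = substr(ref, 101, 400)), ref, "chr1", 1L)
  expect_equal(a3$cigar, "300M")
  expect_equal(a3$pos, 101L)

  # window offset is honoured
  a4 <- spliced_align(c(q = substr(ref, 3001, 3200)),
                      substr(ref, 2501, 4000), "chr1",
                      window_start = 2501L)
  expect_equal(a4$pos, 3001L)
})

test_that("planted gap sizes are recovered across the SV size range", {
  set.seed(11)
  ref <- random_dna(30000)
  for (gap in c(50L, 120L, 1000L, 5000L)) {
    q <- paste0(substr(ref, 10001, 10080),
                substr(ref, 10081 + gap, 10160 + gap))
    a <- spliced_align(c(q = q), ref, "chr1", 1L)
    ev <- call_from_cigar(a)
    expect_equal(ev$svtype, "DEL")
    # placement is left-aligned; junction homology can shift it a few bases
    expect_lte(abs(ev$pos - 10081L), 10L)
    expect_equal(ev$size, gap)
    # deleting the called interval from the reference re-creates the query
    rebuilt <- paste0(substr(ref, 10001, ev$pos - 1),
                      substr(ref, ev$pos + ev$size, 10160 + gap))
    expect_equal(rebuilt, q)
  }
  for (ins in c(50L, 200L, 400L)) {
    q <- paste0(substr(ref, 10001, 10080), random_dna(ins),
                substr(ref, 10081, 10160))
    ev <- call_from_cigar(spliced_align(c(q = q), ref, "chr1", 1L))
    expect_equal(ev$svtype, "INS")
    expect_equal(ev$size, ins)
    expect_lte(abs(ev$pos - 10081L), 10L)
  }
})

test_that("alignment filters drop by mapq, boundary, and fragmentation", {
  base <- data.frame(query_name = "q", chrom = "chr1", pos = 100L,
                     mapq = 60L, cigar = "60M500D60M", n_segments = 1L,
                     boundary_clipped = FALSE, boundary_aligned_len = 60L,
                     aligned_frac = 1, stringsAsFactors = FALSE)
  ok <- filter_alignments(base)
  expect_true(ok$keep)

  low <- base; low$mapq <- 9L
  expect_equal(filter_alignments(low)$drop_reason, "low_mapq")
  expect_true(filter_alignments(transform(base, mapq = 10L))$keep)

  clip <- base; clip$boundary_clipped <- TRUE
  expect_equal(filter_alignments(clip)$drop_reason, "boundary_clipped")

  short <- base; short$boundary_aligned_len <- 10L # e.g. 10M500D60M
  expect_equal(filter_alignments(short)$drop_reason, "short_boundary")
  expect_true(filter_alignments(
    transform(base, boundary_aligned_len = 20L))$keep)

  frag <- base; frag$n_segments <- 6L
  expect_equal(filter_alignments(frag)$drop_reason, "fragmented")
  expect_true(filter_alignments(transform(base, n_segments = 5L))$keep)
})

test_that("CIGAR evidence extraction matches an independent walker", {
  cases <- data.frame(
    query_name = c("a", "b", "c", "d"),
    chrom = "chr1",
    pos = c(1001L, 1001L, 500L, 2000L),
    cigar = c("60M500D60M", "60M35I60M", "150M",
              "10S50M200N40M12I30M5S"),
    stringsAsFactors = FALSE)
  ev <- call_from_cigar(cases)
  # worked examples
  expect_equal(ev$pos[ev$query_name == "a"], 1061L)
  expect_equal(ev$size[ev$query_name == "a"], 500L)
  expect_equal(ev$svtype[ev$query_name == "b"], "INS")
  expect_equal(ev$pos[ev$query_name == "b"], 1061L)
  expect_false("c" %in% ev$query_name)
  # every record agrees with the oracle walker
  for (i in seq_len(nrow(cases))) {
    want <- oracle_cigar_walk(cases$pos[i], cases$cigar[i])$events
    got <- ev[ev$query_name == cases$query_name[i], , drop = FALSE]
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$svtype[k], want[[k]]$type)
      expect_equal(got$pos[k], as.integer(want[[k]]$pos))
      expect_equal(got$size[k], as.integer(want[[k]]$size))
    }
  }
  expect_error(call_from_cigar(data.frame(
    query_name = "x", chrom = "chr1", pos = 1L, cigar = "abc",
    stringsAsFactors = FALSE)), "CIGAR")
})

test_that("evidence clustering merges compatible records and applies X", {
  mk_ev <- function(pos, size, reads, svtype = "DEL") {
    data.frame(svtype = svtype, chrom = "chr1", pos = pos, size = size,
               source = "RAW_CLIP", query_name = reads, reads = reads,
               stringsAsFactors = FALSE)
  }
  ev <- mk_ev(c(1059L, 1060L, 1061L, 1062L), c(498L, 500L, 501L, 502L),
              paste0("r", 1:4))
  calls <- cluster_evidence(ev, X = 3L)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, 4L)
  expect_equal(calls$pos, 1060L)  # median (rounded)

  expect_equal(nrow(cluster_evidence(ev[1:2, ], X = 3L)), 0)

  # incompatible sizes at the same position stay separate
  two <- rbind(mk_ev(rep(1000L, 3), rep(100L, 3), paste0("a", 1:3)),
               mk_ev(rep(1000L, 3), rep(300L, 3), paste0("b", 1:3)))
  calls2 <- cluster_evidence(two, X = 2L)
  expect_equal(nrow(calls2), 2)
  expect_setequal(calls2$size, c(100L, 300L))

  # an extended sequence counts its two constituent reads
  ext_ev <- mk_ev(rep(1000L, 2), rep(100L, 2), c("m1,s1", "m2,s2"))
  expect_equal(cluster_evidence(ext_ev, X = 4L)$support, 4L)

  # the SV size cut removes sub-50 bp records unless disabled
  small <- mk_ev(rep(1000L, 3), rep(30L, 3), paste0("s", 1:3))
  expect_equal(nrow(cluster_evidence(small, X = 2L)), 0)
  expect_equal(nrow(cluster_evidence(small, X = 2L, min_size = NA)), 1)
})

test_that("the minimap2 backend reports a spliced deletion alignment", {
  set.seed(12)
  ref <- random_dna(12000)
  q <- paste0(substr(ref, 5001, 5100), substr(ref, 5601, 5700))
  a <- spliced_align(c(q1 = q), ref, "chr1", 1L, backend = "minimap2")
  expect_gte(nrow(a), 1)
  ev <- call_from_cigar(a)
  ev <- ev[ev$svtype == "DEL", , drop = FALSE]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$size, 500L)
  expect_lt(abs(ev$pos - 5101L), 5)
})
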