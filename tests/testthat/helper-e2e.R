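# Memoized end-to-end fixture: a 2 Mb toy chromosome with 40 deletions
# (100-5000 bp), 40 insertions (60-800 bp) and 10 inversions spiked at
# mixed genotypes, 2 x 150 bp reads at 30x with 0.002 substitution errors,
# aligned with bwa mem and called once. Built on first use and shared by
# every test that needs it.
.e2e_cache <- new.env(parent = emptyenv())

e2e_fixture <- function() {
  if (!is.null(.e2e_cache$result)) return(.e2e_cache$result)
  dir <- file.path(tempdir(), "clipcall-e2e")
  dir.create(dir, showWarnings = FALSE)
  set.seed(100)
  ref <- clipcall::simulate_reference(1, 2e6, n_repeats = 10, seed = 100)
  ev <- clipcall::simulate_sv_events(ref, n_del = 40, n_ins = 40,
                                     n_inv = 10, seed = 101)
  gt <- clipcall::assign_genotypes(nrow(ev), seed = 102)
  gen <- clipcall::spike_svs(ref, ev, gt)
  rd <- clipcall::simulate_reads(gen, coverage = 30, read_len = 150,
                                 error_rate = 0.002, seed = 103,
                                 out_prefix = file.path(dir, "sim"))
  ref_fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(ref, ref_fa)
  Rsamtools::indexFa(ref_fa)
  bam <- file.path(dir, "sim.bam")
  clipcall::align_reads(ref_fa, rd$fastq1, rd$fastq2, bam)
  run <- clipcall::run_caller(bam, ref_fa)
  .e2e_cache$result <- list(run = run,
                            truth = clipcall::truth_calls(gen$truth),
                            genome = gen, bam = bam, ref_fa = ref_fa)
  .e2e_cache$result
}
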