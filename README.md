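# clipcall

Structural variants (SVs) — deletions, insertions, inversions and
translocations of 50 bp and more — are hard to see in paired-end short
reads: a 150 bp read rarely spans an SV junction cleanly, and standard
callers built on split reads and discordant pairs are strongly biased
toward deletions. `clipcall` is an R implementation of a clipped-read-first
calling strategy for coordinate-sorted BAM files, aimed at genomicists who
want a transparent, fully scriptable caller plus a matching spike-in
simulator and benchmarking harness in one package.

## Method

The caller starts from **soft-clipped reads**, the single most sensitive SV
signal in short-read alignments. Per 1 Mb chunk it:

1. estimates the insert-size distribution (mean, population sd over |TLEN|
   of mapq-60 leftmost mates) and sets the support threshold
   `X = max(2, ceil(0.10 × coverage))`;
2. classifies imperfect alignments into clipped / split / discordant
   (`|TLEN| > min(mean + sd, mean + 300)`) / cross-chromosome /
   same-orientation pair / mate-unmapped signals, and clusters clip
   breakpoints (5 bp diameter, ≥ X reads) into candidates;
3. **extends reads**: an SM-clipped read (5′ clip) is concatenated with an
   MS-clipped read (3′ clip) within 1 kb when the first *n* bases of one
   match the last *n* of the other (*n* from `read_length − 30` downward,
   strictly > 30, up to 3 mismatching bases tolerated at each overlap
   boundary);
4. aligns raw clipped reads and extended sequences in **spliced
   (large-gap) mode** — a builtin 15-mer seed-and-chain aligner by default,
   minimap2 optionally — and reads deletions (`D`/`N` ops) and insertions
   (`I` ops) off the CIGARs, after dropping alignments with mapq < 10,
   clipped boundaries, terminal blocks < 20 bp, or > 5 segments;
5. calls inversions from orientation-flipped split reads and
   same-orientation pairs (support ≥ X), and translocations from
   cross-chromosome splits (mapq > 20 both sides) and pairs
   (combined support ≥ 2X), emitted as reciprocal BND records;
6. resolves each insertion candidate through a **decision tree** —
   alignment CIGAR → spliced alignment → local de Bruijn assembly
   (k = 41, 61, 81) → complex-read-alignment rescue (mapq ≥ 50,
   high-quality-base ratio ≥ 0.8, mates unmapped or on other
   chromosomes) — terminating at the first node that succeeds and vetoing
   candidates within 200 bp of a deletion/inversion/translocation call.

Evaluation follows the standard windowed rule: a call matches a truth event
when breakpoints agree within ±200 bp and (when both known) sizes differ by
less than 50% of the truth size;
`F1 = 2·sensitivity·precision / (sensitivity + precision)`.

## Worked example

Simulate a 300 kb toy genome with spiked SVs, align with bwa, call, and
benchmark:

```r
library(clipcall)
ref <- simulate_reference(1, 3e5, n_repeats = 2, seed = 11)
ev  <- simulate_sv_events(ref, n_del = 6, n_ins = 6, n_inv = 2, seed = 12)
gen <- spike_svs(ref, ev, assign_genotypes(nrow(ev), seed = 13))
rd  <- simulate_reads(gen, coverage = 30, read_len = 150, seed = 14,
                      out_prefix = tempfile())
Biostrings::writeXStringSet(ref, "ref.fa")
align_reads("ref.fa", rd$fastq1, rd$fastq2, "sim.bam")
run <- run_caller("sim.bam", "ref.fa", out_vcf = "calls.vcf")
match_calls(run$calls[run$calls$svtype == "DEL", ],
            truth_calls(gen$truth) |> subset(svtype == "DEL"), "DEL")$result
```

On this seed the run prints

```
<clipcall_run> 14 call(s)
DEL INS INV
  6   6   2
<sv_eval> tp=6 fp=0 fn=0 sensitivity=1.000 precision=1.000 f1=1.000
```

i.e. all six deletions are recovered at the exact breakpoints (support
7–27 reads each), the six insertions resolve across the spliced and
assembly decision nodes, and both inversions are spanned within a few
bases. A command-line interface with the same three stages is installed as
`exec/clipcall` (`clipcall call|sim|eval`).

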