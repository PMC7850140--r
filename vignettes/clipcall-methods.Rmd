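---
title: "Clipped-read SV calling: models, parameters and design choices"
author: "clipcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clipped-read SV calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Structural variants (≥ 50 bp) interrupt the collinearity between a sample
genome and its reference. In paired-end short-read data the interruption
leaves several footprints: reads crossing a junction are soft-clipped;
some are split into a primary plus supplementary alignment; read pairs
straddling a deletion show inflated insert sizes; pairs straddling an
inversion come out in the same orientation; pairs straddling a
translocation land on two chromosomes; and reads born inside novel
inserted sequence fail to map at all, leaving mapped mates with lost
partners. Clipped reads are the most abundant and least biased of these
signals — they appear at both deletion and insertion junctions — and
`clipcall` is organized around them.

# Pipeline model

## Library statistics

Per 1 Mb chunk the insert-size mean and standard deviation are estimated
from primary, non-duplicate reads with mapping quality exactly 60,
counting each pair once through its leftmost mate (TLEN > 0). The standard
deviation is the population form: at chunk scale the difference from the
sample form is negligible and the population form makes tiny test
fixtures exactly checkable. The read length is the longest
soft-clip-excluded aligned length observed, and coverage is aligned bases
over chunk width. A chunk with no qualifying pairs reuses the previous
chunk's estimate (there is no principled local estimate to prefer).
Duplicate-flagged reads are dropped everywhere; duplicate *marking* is
trusted from the input BAM.

The central tuning constant is the support threshold
`X = max(2, ceil(support_frac × coverage))` with `support_frac = 0.10`:
every call class requires at least X supporting reads (translocations 2X).
The floor of 2 is a deliberate guard — a single read can never nominate an
event — which matters below ~10× coverage where `ceil(0.1 × cov)` would
otherwise be 1.

## Signal classification and candidates

A read is *clipped* when a terminal clip exceeds 5 bp (strict; the 5 bp
value separates alignment-noise nibbling from junction evidence), *split*
when an SA tag is present, *discordant* when
`|TLEN| > min(mean + sd, mean + 300)` — the 300 bp cap keeps the
threshold meaningful for sloppy libraries with large sd — and an
*inversion pair* when both mates map to one chromosome in the same
orientation. Clip breakpoints are clustered by a greedy left-to-right
sweep with a 5 bp diameter; the representative position is the mode
(ties to the left). The sweep is the simplest order-independent
clustering consistent with a "5 bp region" rule; we read that phrase as a
diameter, since a ±5 radius would let one read support two adjacent
candidates.

## Read extension

Within 1 kb, an SM-clipped read (clip on the 5′ side) is compared against
each MS-clipped partner: the first *n* bases of the SM read against the
last *n* of the MS read, from `n = read_length − 30` downward, accepting
the first (largest) *n* strictly greater than 30. Up to 3 bases at each
end of the compared window may mismatch — sequencing errors concentrate at
clip boundaries — but the interior must match exactly, which keeps the
operation property-testable against a brute-force oracle. Inside the
overlap the MS read's bases win (the choice is arbitrary and only matters
when the boundary discount hid a mismatch). Each SM read contributes at
most one join (largest *n*, ties to the leftmost partner breakpoint):
allowing all pairs would double-count evidence downstream.

One guard goes beyond the plain search: a pair that verifies at *more
than one* candidate *n* has a periodic overlap (tandem repeat content).
The true join length is then undecidable, and concatenating at the wrong
*n* produces a chimera that collapses repeat copies — in practice this
showed up as insertion calls at the right position with roughly halved
sizes. Ambiguous pairs are therefore not extended; their raw clipped
reads still reach the assembly node, which handles repeats explicitly.

The guard cannot catch every repeat chimera (a short clip can leave only
one admissible overlap), so the decision tree applies a complementary
rule at its CIGAR and spliced nodes: when the clipped sequences
supporting a candidate are themselves tandem-periodic (the sequence
matches itself shifted by ≤ 25 bp at ≥ 90% identity), the junction
content is a repeat array whose copy number no read-scale alignment can
count. The insertion is still called at the breakpoint, but its size is
masked and the record flagged IMPRECISE — the same size-unknown
convention used for partially assembled insertions, and the honest
statement of what 150 bp reads can resolve there.

## Spliced alignment

Raw clipped reads and extended sequences are realigned in spliced mode —
the alignment class that tolerates large reference gaps within one query,
originally built for exons and equally suited to SV junctions. The
builtin backend indexes the candidate's reference window (±50 kb; all
queries originate from clipped reads anchored there) with exact 15-mers,
merges co-diagonal seeds, chains colinear segments, and emits `D` for a
reference gap, `I` for a query gap and `M` between. Two numerical
choices: overlapping neighbour segments are trimmed on the *left*
segment's end so placement-ambiguous gaps come out left-aligned (the
convention of production aligners; without it, junction homology makes
gap placement depend on which random seed extended further), and up to 3
unmatched terminal bases are absorbed into the terminal match block,
mirroring affine end alignment — otherwise a single sequencing error in
the last bases would soft-clip the boundary and the alignment would be
discarded by the boundary filter. Exact recovery of planted gaps is
guaranteed only up to junction homology: the left-aligned position can
sit a few bases left of the planted coordinate while describing the
identical edit, which is why tests assert edit equivalence plus a small
position band. `minimap2` is available as an external backend for
whole-genome use; the builtin one keeps the test suite hermetic.

Alignments are dropped when mapq < 10, a boundary is clipped, a terminal
aligned block is shorter than 20 bp, or the query fragments into more
than five regions. Gap evidence of the same type within 10 bp and 20%
size merges into a call (median position and size; support = distinct
reads, an extended sequence counting its two constituents); calls need
support ≥ X and size ≥ 50 bp — smaller events are indels, not SVs. The
10 bp / 20% merge tolerances are deliberately much tighter than the
±200 bp evaluation window: they only need to absorb breakpoint jitter
from alignment ambiguity, not assign calls to truth.

## Insertion decision tree

Each clip-supported candidate is tested by four methods in a fixed order,
terminating at the first success: (1) `I`/`D` ops in the original
alignments — an `I` ≥ 50 bp with X-fold support is an exact call, while an
X-supported indel < 50 bp *explains* the candidate and stops the tree;
(2) an insertion call from the spliced pipeline within 200 bp; (3) local
de Bruijn assembly; (4) complex-alignment rescue: clipped reads with
mapq ≥ 50 and a mapped high-quality-base ratio ≥ 0.8 whose mates are
unmapped or on other chromosomes — the signature of inserted sequence the
aligner cannot place. The small-indel termination requires X reads, the
same bar as every other node, for symmetry; the order itself encodes
increasing cost and decreasing precision of the methods. Candidates
within ±200 bp of a deletion, inversion or translocation call are
explained by that event; we apply this veto before the assembly node
rather than only inside node 4 — under the ≥ 1 kb event-separation of the
simulations it cannot change the call set (no true insertion hides within
200 bp of another event), and it saves the most expensive node where the
outcome is already determined.

The mate-on-other-chromosome criterion in node 4 deliberately accepts
mates below the translocation mapping-quality bar: inserted sequence with
partial similarity elsewhere produces exactly such low-confidence
cross-chromosome mates, and true translocations are separated by the 2X
support requirement and the exclusion veto.

## Local assembly

Around each unresolved candidate, a 1.2 kb window of clipped and
improperly paired reads (mapq ≥ 20) plus their mates — including unmapped
mates, which carry the insert's interior — is assembled with a node-centric
de Bruijn graph for k ∈ {41, 61, 81}, pooling contigs across k without
deduplication (clustering absorbs redundancy). Edges require an observed
(k+1)-mer; nodes need count ≥ 2 (a lone read never yields a contig); tips
shorter than 2k are clipped and simple bubbles popped keeping the
higher-coverage arm (ties broken lexicographically for determinism).
These are conventional short-read assembler defaults; the assembler is
calibrated only by the planted-insertion recovery property in the test
suite (≥ 90% of 100–400 bp inserts recovered exactly across 50 seeded
fixtures). Contigs realigned over the breakpoint window yield a *full*
insertion (an `I` op ≥ 50 bp within 200 bp of the candidate, exact size)
or a *partial* one (a contig clip > 50 bp at the candidate; size unknown,
flagged IMPRECISE); full beats partial.

## Inversions and translocations

A split read whose primary and supplementary alignments sit on one
chromosome with opposite strands spans an inversion; the junction on each
side is the reference boundary adjacent to that alignment's larger clip,
read from the CIGAR (primary) and the SA tag (supplementary).
Same-orientation pairs support larger inversions with only bracketing
information: breakpoints are estimated by pushing the outer mate
positions outward by half the insert-size deficit — a concrete reading of
"infer from observed versus expected insert size"; any estimate within
200 bp of a clipped-read breakpoint snaps to it, and snapping dominates
whenever clips exist, which bounds the formula's influence. Clusters need
X mixed split/pair supporters. Because pair estimates can snap to
different clips and fragment one event, inversion calls with ≥ 50%
reciprocal overlap collapse onto the best-supported record.
Translocations require mapq > 20 on both split sides, combined
split + pair support ≥ 2X, and are emitted as reciprocal BND pairs with
cross-referencing MATEID.

# The simulator

The simulator is the package's benchmarking substrate, not a test
convenience: its defaults are the study conditions. A diploid genome is
built by applying each event to haplotype 1, 2 or both according to
genotypes drawn uniformly from {1|1, 0|1, 1|0} (expected
homozygous:heterozygous ratio 1:2). Events keep ≥ 1 kb separation;
insertions of 60–800 bp (30% tandem 20-mer arrays, mimicking the
repeat-enriched content of real insertions), deletions of 100–5000 bp,
inversions of 50 bp–10 kb. Translocations follow the benchmark design:
per haplotype, 10 disjoint chromosome pairs with 3 reciprocal exchanges
each — segments alternating between the derived chromosomes at ascending
cut points — giving 60 breakpoints per haplotype, always heterozygous.
Cut points are drawn in reference coordinates (≥ 1 kb from ends and other
events) and mapped through the haplotype's indels, so the truth table
stays in reference coordinates.

Reads are drawn per haplotype (insert ~ Normal(500, 50) bp truncated at
the read length, either strand), with per-base substitution errors at
0.002 and low Phred values (2–15) on erroneous bases versus 30–40
elsewhere — enough structure for the high-quality-base-ratio filters to be
exercised. Indel sequencing errors are not modeled: at a 0.002
substitution-dominated error setting their effect on 15-mer seeding and
41+-mer assembly is second-order. Everything is reproducible from the
seed. What the simulator does *not* emulate: real base-quality profiles,
PCR duplicates, chimeric library artifacts, heterozygous SNP background,
and genome-scale repeat families (only local tandem arrays). Passing the
end-to-end regression therefore demonstrates the pipeline's mechanics
under controlled junction structure, not field performance on a human
genome.

# Evaluation

A call matches a truth event of the same type when breakpoints agree
within ±200 bp and, when both sizes are known, the size difference is
strictly below 50% of the truth size (the truth size is the denominator);
size-unknown insertion calls and translocation breakpoints match on the
window alone. Assignment is greedy nearest-first and one-to-one — the
window rule defines compatibility, not assignment, so the greedy choice is
verified against a brute-force maximum bipartite matching oracle on small
instances. Tandem-duplication truth entries are relabeled as insertions
before matching. Extra calls on one truth event count as false positives
(no deduplication credit). Sensitivity is TP over truth, precision TP
over calls, `F1 = 2sp/(s+p)` with 0 when both vanish.

# Problem sizes used by the shipped checks

The test suite runs the caller end to end on a seeded 2 Mb single
chromosome (40 deletions, 40 insertions, 10 inversions, 30×, 2×150 bp,
0.002 errors) — large enough for chunked processing and every decision
node to fire, small enough to rerun routinely — asserting deletion
sensitivity ≥ 0.85, insertion sensitivity ≥ 0.70 and precision ≥ 0.90
as regression floors, plus the strict additivity of the decision tree
over its spliced node alone. The acceptance script uses a 1 Mb genome
(20 + 20 + 5 events) for the same measurement, a 20 × 50 kb genome for
the translocation design counts, and a 20 × 300 kb genome for the 200
default inversions. Inversion placement at 50 bp–10 kb needs roughly
1.5 Mb of clear sequence per 200 events; the 6 Mb toy leaves comfortable
headroom.

# Known limitations

No CRAM input, no genotyping of calls, no read-depth signal, no
distinction of tandem duplications from insertions, and no nested or
complex rearrangement reconstruction. The builtin spliced aligner
reports a fixed mapping quality (60) — placement ambiguity in repeats is
modeled only through seed masking and the external minimap2 backend.
Chunk-level parallelism (`threads`) relies on forked workers and an
order-canonicalized merge; output is independent of worker count.
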