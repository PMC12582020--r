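---
title: "Quantifying tRNA expression and modifications from nanopore reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tRNA expression and modifications from nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Mature human tRNAs are short (~76 nt), heavily modified, and encoded by
hundreds of genes that collapse to a much smaller set of distinct body
sequences — some differing by a single nucleotide. Direct RNA nanopore
sequencing reads them natively, which preserves modification signals but
creates two analysis problems that this package addresses:

1. **Multi-mapping.** Against a reference of near-identical sequences, a
   short-read aligner reports many reads at mapping quality (MAPQ) 0 even
   when the primary alignment scores strictly better than every
   alternative, because MAPQ is penalized for the mere existence of
   alternatives. Discarding MAPQ-0 reads would discard a large fraction of
   the usable data.
2. **Modification inference.** Modified ribonucleotides perturb the pore
   current and produce systematic base-calling errors (mismatches and
   deletions) at and around their positions, and modern base-callers
   additionally emit per-base modification probabilities. Both signals
   need position-resolved aggregation, filtering and comparison against
   orthogonal chemistry-based site tables before they are interpretable.

## Reference curation

The gene set (FASTA plus a tRNAviz-style annotation table) is collapsed to
unique body sequences by exact sequence identity; each unique sequence
keeps the lexicographically smallest member gene id as its `seq_id`, so
the curated reference is reproducible run to run. For the hg19 human set
this collapse takes 414 genes to 267 unique sequences across 47
isoacceptors. Unique sequences are then padded with the library adapter
sequences on both sides — reads run from the tRNA body into the ligated
adapters, and padding lets the aligner place those bases instead of
soft-clipping into oblivion. The 3' CCA status of the input sequences is
taken as given; nothing is appended.

Sprinzl numbering — the canonical tRNA coordinate system that makes
"position 34" mean the wobble base on every tRNA regardless of indels in
the alignment — is *input data*: the annotation table carries one label
per base (curated upstream from the literature and modification
databases), and the package only builds the forward and inverse maps.
Positions in the adapter pads map to the sentinel `"not-in-body"`; a label
a tRNA lacks (e.g. e-arm labels on type I tRNAs) is an absent value, not
an error. Internally all coordinates are 0-based half-open; SAM (1-based)
and bedMethyl (0-based) are converted at the I/O boundary.

## MOD-MAPQ and read assignment

For each read, let `d = AS_primary - max(AS_alternatives)` over the
scored secondary records. If `d > 0` and `d` exceeds the reported MAPQ,
the mapping quality becomes `d`, capped at 60 to stay in the conventional
MAPQ range. With no scored alternatives the original value stands. The
recalibrated file is byte-identical to the input except for this one
field on primary mapped records, so modification tags (MM/ML) survive
untouched.

Reads still at MAPQ 0 are rescued by inspecting the *tie set* — all hits
whose alignment score equals the primary's, by strict equality on the raw
aligner scores (scores are integers in aligner units; recalibration does
not alter them, and using post-hoc quantities in the tie test would make
classification depend on its own output). If the tie set names one
reference sequence the read is `same_target`; one anticodon across
several sequences, `same_codon`; otherwise `ambiguous`. Reverse-strand
primaries are `antisense` — a proxy for mis-mapping, since the library
chemistry sequences the sense strand.

## Quantification

Counting uses forward-strand reads whose mean base-call quality exceeds
4.0 (Phred). We read the upstream "quality score" filter as *base-call*
quality rather than mapping quality because a MAPQ reading would
contradict the deliberate counting of MAPQ-0 rescue categories in the
same procedure; both thresholds are exposed (`min_read_qual`, and the
mapq structure of the bins) so either reading is reproducible. Counts are
kept per (anticodon, MOD-MAPQ bin, category) for QC; the expression
matrix sums the MAPQ>0 bins plus the MAPQ-0 `same_codon` bin. MAPQ-0
`same_target` reads are included by default — they identify a single
tRNA, hence a single anticodon — with `include_same_target = FALSE`
giving the strict same-codon-only reading. Ambiguous reads are never
counted. Columns are normalized to a fixed sum of 1000, which is
scale-free: multiplying a column by any positive constant leaves its
normalized values unchanged.

## Base-calling-error statistics

Pileups are computed with Rsamtools on the recalibrated BAM using reads
with (adjusted) MAPQ >= 1, base quality >= 2, and a per-position depth cap
of 50000 (a cap, not a sample: positions deeper than the cap keep their
first-come reads in BAM order, which is deterministic for a given file).
Per position:

- `relative_error = (mismatches + deletions) / (matches + mismatches + deletions)`
- `ref_base_fraction = ref-base count / (matches + mismatches + deletions)`

Insertions are tracked but excluded from both numerator and denominator;
deletions are counted at every deleted reference position, insertions
attributed to the base left of the insertion point. Deletions belong in
the error numerator — the event list defining the denominator includes
them, and a flag exists to drop them for sensitivity analyses. The two
statistics share a denominator and have complementary numerators, so they
sum to exactly 1 — a property the test suite checks on 10^5 randomized
pileups. Positions with fewer than 80 events are excluded from every
downstream table.

Condition comparisons take `log2(mean_exp / mean_ctrl)` of replicate-mean
relative errors, restricted to positions passing the 80-event filter in
*every* replicate of both conditions — the intersection rule avoids
artifacts from comparing different position sets. A zero control mean
yields an infinity sentinel rather than a silently pseudo-counted value;
an optional pseudo-count exists for plotting. The global test groups
relative errors of all tRNA sequences per Sprinzl label (all labels
present in both conditions are tested — no curated subset is assumed) and
runs a two-sample t-test per label, Welch by default (the safer choice
under unequal variances; `var_equal = TRUE` gives the pooled test), with
Benjamini–Hochberg adjustment across labels. Degenerate groups (both
constant) return t = 0, p = 1 when equal rather than erroring.

## Modification pileups

modkit-dialect bedMethyl records are kept when they are on the plus
strand, their canonical base matches the reference base at the call
position, and they carry at least 100 valid calls (confidently modified
or unmodified). Per-site modification probability is the unweighted mean
of the per-sample modified fraction over an explicit sample set
(typically untreated wild-type samples; membership comes from a sample
sheet, never from file-name parsing). Threshold cutoffs (0%, 10%, 20%)
use strict inequality — a site at exactly 10% is excluded at the 10%
cutoff — and the comparison is done on the fraction scale so that the
cutoff and a stored probability share one binary representation
(`0.1 > 10/100` is reliably false, whereas `100 * 0.1 > 10` is not).
Threshold sets are therefore nested by construction.

Cross-method comparison keys sites on (tRNA identifier, Sprinzl label).
Because orthogonal tables are typically reported per isoacceptor while
nanopore sites are per isodecoder, the default roll-up takes the maximum
mean probability across isodecoders of an anticodon, with per-isodecoder
rows retained; both key spaces are available since neither is canonical.
Orthogonal tables are pre-filtered at a method-appropriate rate (0 for
bisulfite m5C tables, which report all sites; 10% for cyclization-based
pseudouridine tables, whose high-confidence sites exceed 10%), and
orthogonal rows that cannot be mapped into the reference are listed in an
unmapped report, never silently dropped. Known base-caller isomer
confusions — m3C at position 32 and m1A at 58 read as m5C and m6A — are
documented caveats, not corrected for.

## The synthetic-data generator

The generator emits every input the pipeline consumes with recorded
ground truth: a gene set with exact duplicate copies and isodecoders one
substitution apart; aligned reads with alignment scores, co-optimal
secondary hits planted to produce each rescue category, antisense
contamination, and per-position mismatch/deletion noise; and bedMethyl
files with binomially sampled modified fractions. All randomness flows
from one seed; a fixed seed reproduces every file byte-for-byte.

Default study conditions, chosen once: 6 isoacceptors x 2 isodecoders x 2
duplicate copies; 2000 reads per sample; antisense rate 0.05 (the current
chemistry leaves a small antisense residual); same-target and same-codon
rates 0.05 each and ambiguous 0.02 (enough planted mass to test every
rescue path); baseline per-position error 0.08, realistic for direct RNA
base-calling over heavily modified tRNA, with a 4x multiplier planted at
Sprinzl 37 of Phe-GAA in the "experimental" condition — mimicking the
hypermodified guanosine-37 neighbourhood whose error rate tracks the
modification state; m5C at position 48 (fraction 0.8) and pseudouridine
at 55 (0.9) for the bedMethyl path. Alignment scores use a simple
`matches - 2*(mismatches+deletions)` scheme documented in the SAM header;
only score *differences* matter to MOD-MAPQ, so affine-gap realism is
deliberately not modelled.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: raw-signal (squiggle) behaviour, sequence- and
neighbour-dependent error structure, base-caller-specific deletion
patterns around modified bases, partial-length reads from pore stalls,
and real aligner score landscapes. Recovery of planted truth demonstrates
that the bookkeeping and statistics are correct, not that biological
modification calls are accurate.

## Test and verification scale

The test suite verifies the recalibration rule exhaustively over its
sufficient statistic (primary score x best alternative score x original
MAPQ on [0,20]^2 x [0,60]) plus thousands of random full hit lists
against a brute-force transcription of the rule; classification against
planted truth on a 10,000-read study; the error-spike recovery at ~5000x
per-position depth with two replicates per condition (the spiked label's
mean log2 ratio lands within 0.1 of log2(4)); Welch/BH agreement with
closed-form references at 1e-10 and false-discovery control on 100 null
simulations; and the modification-pileup set logic on constructed
fixtures. These sizes were chosen as the smallest at which the sampling
error of each recovered quantity is comfortably inside its assertion
band.

## Known limitations

- Alternative hits must be present as scored secondary records; the
  XA-tag dialect carries no alignment scores and is not used.
- The classifier trusts the aligner's score model; co-optimal hits the
  aligner failed to report cannot be rescued.
- Error-based inference cannot see modifications that do not perturb
  base-calling (e.g. small chemical groups), and neighbouring
  modifications blur single-nucleotide attribution.
- Isomeric modifications are not distinguishable from the base-caller's
  probabilities; sites at known isomer positions should be read with
  that in mind.
- Differential expression is exported as counts for external tools, not
  computed here.
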