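# nanotrna

Post-processing for nanopore direct RNA sequencing of human transfer RNAs:
tRNA expression quantification and modification inference from aligned
reads.

Mature tRNAs are short, heavily modified, and encoded by gene sets that
collapse to far fewer unique body sequences, some a single nucleotide
apart. Two consequences dominate the analysis. First, short-read aligners
report many tRNA reads at mapping quality 0 despite a strictly best
primary alignment, because MAPQ is penalized for the existence of
alternatives. Second, modified ribonucleotides perturb the pore current,
so modifications surface both as systematic base-calling errors and as
per-base modification probabilities from the base-caller.

The package implements, for users of tRNA-seq data in R:

- **Reference curation** — collapse a tRNA gene set to unique sequences
  (e.g. 414 hg19 genes → 267 unique sequences, 47 isoacceptors), attach
  anticodon/isotype and Sprinzl position maps, pad with library adapters,
  write the alignment reference and lookup tables.
- **MOD-MAPQ recalibration** — with `d = AS_primary − AS_best_alt` over a
  read's scored alternative hits, the mapping quality is raised to `d`
  (capped at 60) whenever `d > 0` exceeds the reported MAPQ. Remaining
  MAPQ-0 reads are rescued as `same_target` / `same_codon` when every
  equal-top-score hit names one reference sequence / one anticodon.
- **Quantification** — per-(anticodon, MAPQ-bin, category) QC counts;
  expression matrix summing MAPQ>0 and rescued MAPQ-0 reads; fixed-sum
  normalization to 1000 per sample; proper/antisense mapping QC.
- **Error profiling** — per-position pileups (via Rsamtools) with
  `relative_error = (mismatch + deletion) / (match + mismatch + deletion)`,
  its complement `ref_base_fraction`, condition log2 ratios, and
  per-Sprinzl-position Welch t-tests with Benjamini–Hochberg correction.
- **Modification pileups** — modkit-dialect bedMethyl parsing; plus-strand
  / reference-match / ≥100-valid-call filtering; per-site probability
  averaging across samples; strict 0/10/20% cutoffs; overlap comparison
  against orthogonal site tables (bisulfite m⁵C, cyclization Ψ).
- **Synthetic data** — a deterministic generator for every input format
  with recorded ground truth, so the full pipeline is testable offline.

## Worked example

Simulate a two-replicate study, recalibrate, assign and quantify:

```r
library(nanotrna)

cfg <- simulation_config(seed = 42, reads_per_sample = 4000)
ref <- simulate_reference(cfg, "genes")
bundle <- curate_reference(ref$fasta, ref$annotation,
                           cfg$adapter5, cfg$adapter3, out_dir = "reference")

asn <- list()
for (i in 1:2) {
  s <- paste0("rep", i)
  simulate_alignments(bundle, cfg, s, "control", paste0(s, ".sam"), i)
  asn[[s]] <- process_alignments(paste0(s, ".sam"), bundle$anticodon_lookup,
                                 sam_out = paste0(s, ".recal.sam"))
}
table(asn$rep1$category)
#>   ambiguous   antisense  same_codon same_target      unique
#>          76         178         194         217        3335
mapping_qc(asn$rep1)
#>   n_mapped n_unmapped fraction_proper fraction_antisense
#> 1     4000          0          0.9555             0.0445

norm <- normalize_fixed_sum(expression_matrix(lapply(asn, count_per_mapq_bin)))
round(norm, 1)
#>          rep1  rep2
#> Arg-TCT 147.9 149.0
#> Asp-GTC 105.4 107.0
#> Glu-TTC 175.1 176.4
#> Gly-GCC 194.6 194.9
#> Lys-TTT 145.5 144.1
#> Phe-GAA 231.4 228.6
```

Reading the output: 411 of the 4000 reads arrived at MAPQ 0 with
co-optimal alternative hits and were rescued (`same_target` +
`same_codon`) instead of discarded; 178 reverse-strand reads are flagged
antisense (4.45% — the mis-mapping proxy); each normalized column sums to
1000, so values are relative anticodon abundances comparable across
samples — here the planted expression gradient (Phe-GAA highest) is
recovered, and `round(cor(norm[,1], norm[,2]), 3)` printed `1`,
reflecting near-perfect replicate agreement at this depth.

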