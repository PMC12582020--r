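# Shared fixtures, all built in code at test time.

write_toy_gene_set <- function(dir,
                               genes = data.frame(
                                 gene_id = c("gA1", "gA2", "gB1", "gB2", "gC1"),
                                 sequence = c("GGGCCCATTCCA", "GGGCCCATTCCA",
                                              "GGGTTTATTCCA", "GGGTTTATTCCA",
                                              "GGGAAAATTCCA"),
                                 isotype = c("Gly", "Gly", "Gly", "Gly", "Arg"),
                                 anticodon = c("GCC", "GCC", "GCC", "GCC", "TCT"),
                                 sprinzl = rep(paste(1:12, collapse = ","), 5),
                                 stringsAsFactors = FALSE)) {
  fasta <- file.path(dir, "genes.fasta")
  writeLines(paste0(">", genes$gene_id, "\n", genes$sequence), fasta)
  annot <- file.path(dir, "genes.tsv")
  write.table(genes[, c("gene_id", "isotype", "anticodon", "sprinzl")],
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, annotation = annot, genes = genes)
}

# one-record SAM writer for hand-built alignment cases
sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq, qual,
                       tags = character()) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual, tags),
        collapse = "\t")
}

write_sam <- function(path, sq, records) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)),
               records), path)
}

# assignments-row builder for quantification tests
assignment_rows <- function(n, category, anticodon, mod_mapq,
                            strand = "+", qual = 20) {
  data.frame(read_id = sprintf("r%03d_%s", seq_len(n), category),
             category = category, anticodon = anticodon,
             target_id = NA_character_, strand = strand,
             original_mapq = 0L, mod_mapq = mod_mapq,
             mean_base_quality = qual, n_alternatives = 0L,
             stringsAsFactors = FALSE)
}

# single bedMethyl record in the package's internal layout
bed_record <- function(seq_id = "t1", start = 5L, code = "m", n_valid = 200L,
                       n_mod = 50L, strand = "+") {
  data.frame(seq_id = seq_id, start = start, strand = strand,
             mod_code = code,
             mod_type = unname(c(m = "m5C", a = "m6A",
                                 `17802` = "pseU")[code]),
             canonical_base = unname(c(m = "C", a = "A",
                                       `17802` = "T")[code]),
             n_valid = n_valid, n_mod = n_mod,
             n_canonical = n_valid - n_mod, stringsAsFactors = FALSE)
}

# random pileup rows with exact count bookkeeping
random_pileups <- function(n, max_count = 50L, seed = 1L) {
  set.seed(seed)
  counts <- matrix(sample(0:max_count, 5L * n, replace = TRUE), ncol = 5L)
  df <- data.frame(seq_id = "s", pos = seq_len(n) - 1L,
                   ref_base = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   A = counts[, 1], C = counts[, 2], G = counts[, 3],
                   T = counts[, 4], del = counts[, 5],
                   ins = sample(0:max_count, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df$total_events <- df$A + df$C + df$G + df$T + df$del
  df
}

# small simulated study: reference bundle + per-sample SAM + truth
simulate_study <- function(seed = 5L, reads = 600L, dir = NULL,
                           samples = c(s1 = "control", s2 = "control"), ...) {
  if (is.null(dir)) {
    dir <- tempfile("study")
    dir.create(dir)
  }
  cfg <- simulation_config(seed = seed, reads_per_sample = reads, ...)
  ref <- simulate_reference(cfg, file.path(dir, "ref"))
  bundle <- curate_reference(ref$fasta, ref$annotation, cfg$adapter5,
                             cfg$adapter3, out_dir = file.path(dir, "out"))
  sims <- lapply(seq_along(samples), function(i)
    simulate_alignments(bundle, cfg, names(samples)[i], samples[[i]],
                        file.path(dir, paste0(names(samples)[i], ".sam")),
                        sample_index = i))
  names(sims) <- names(samples)
  list(cfg = cfg, ref = ref, bundle = bundle, sims = sims, dir = dir)
}
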