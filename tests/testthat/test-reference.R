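test_that("gene sets parse with annotations attached and U/T normalised", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  genes <- parse_gene_set(toy$fasta, toy$annotation)
  expect_equal(nrow(genes), 5L)
  expect_equal(genes$isotype[genes$anticodon == "GCC"][1], "Gly")
  expect_equal(genes$anticodon[genes$gene_id == "gC1"], "TCT")

  # RNA-alphabet input is normalised to DNA
  writeLines(c(">gU", "GGGUUUAUUCCA"), file.path(dir, "u.fasta"))
  write.table(data.frame(gene_id = "gU", isotype = "Gly", anticodon = "gcc"),
              file.path(dir, "u.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gu <- parse_gene_set(file.path(dir, "u.fasta"), file.path(dir, "u.tsv"))
  expect_equal(gu$sequence, "GGGTTTATTCCA")
  expect_equal(gu$anticodon, "GCC")
})

test_that("parse errors name the offending gene", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  writeLines(c(">orphan", "ACGT"), file.path(dir, "orphan.fasta"))
  expect_error(parse_gene_set(file.path(dir, "orphan.fasta"), toy$annotation),
               "orphan")
  write.table(data.frame(gene_id = "gX", isotype = "Gly", anticodon = "GCCA"),
              file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(">gX", "ACGT"), file.path(dir, "gx.fasta"))
  expect_error(parse_gene_set(file.path(dir, "gx.fasta"),
                              file.path(dir, "bad.tsv")), "anticodon")
})

test_that("deduplication collapses exact copies and partitions the genes", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  genes <- parse_gene_set(toy$fasta, toy$annotation)
  uniq <- deduplicate(genes)
  expect_equal(nrow(uniq), 3L)                       # 2 pairs + 1 singleton
  expect_equal(sum(uniq$n_members), nrow(genes))     # partition property
  expect_setequal(uniq$seq_id, c("gA1", "gB1", "gC1"))  # smallest member id
  expect_equal(attr(uniq, "n_anticodons"), 2L)

  # idempotence: deduplicating the unique sequences is the identity
  again <- deduplicate(data.frame(gene_id = uniq$seq_id,
                                  sequence = uniq$sequence,
                                  isotype = uniq$isotype,
                                  anticodon = uniq$anticodon,
                                  stringsAsFactors = FALSE))
  expect_equal(again$sequence, uniq$sequence)
  expect_equal(again$seq_id, uniq$seq_id)

  conflicted <- genes
  conflicted$anticodon[conflicted$gene_id == "gA2"] <- "TCT"
  expect_error(deduplicate(conflicted), "conflicting anticodon")
})

test_that("random duplicate groups collapse to the planted unique count", {
  # oracle: brute-force hash of sequences
  set.seed(99)
  for (rep in 1:5) {
    n_uniq <- sample(4:12, 1)
    seqs <- replicate(n_uniq, paste(sample(c("A", "C", "G", "T"), 30,
                                           replace = TRUE), collapse = ""))
    copies <- sample(1:4, n_uniq, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(sum(copies))),
      sequence = rep(seqs, copies),
      isotype = "Gly", anticodon = rep("GCC", sum(copies)),
      stringsAsFactors = FALSE)
    expect_equal(nrow(deduplicate(genes)), length(unique(seqs)))
  }
})

test_that("adapter padding preserves the body at the stated offset", {
  uniq <- data.frame(seq_id = "u1", sequence = "GGGCCCATTCCA",
                     anticodon = "GCC", isotype = "Gly",
                     stringsAsFactors = FALSE)
  pad <- build_padded_reference(uniq, "AAAA", "TTTT")
  expect_equal(nchar(pad$padded_sequence), 12L + 8L)
  expect_equal(pad$body_offset, 4L)
  expect_equal(substr(pad$padded_sequence, 5, 16), uniq$sequence)

  none <- build_padded_reference(uniq, "", "")
  expect_equal(none$padded_sequence, uniq$sequence)
  expect_equal(none$body_offset, 0L)
})

test_that("reference FASTA round-trips ids and sequences byte-identically", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  uniq <- deduplicate(parse_gene_set(toy$fasta, toy$annotation))
  pad <- build_padded_reference(uniq, "ACGT", "GT")
  fa <- write_reference_fasta(pad, file.path(dir, "ref.fasta"))
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(names(back), pad$seq_id)
  expect_identical(as.character(back), setNames(pad$padded_sequence,
                                                pad$seq_id))
})

test_that("Sprinzl maps invert exactly and pads hit the sentinel", {
  dir <- withr::local_tempdir()
  labels <- c("1", "2", "3", "20a", "e11", "34", "37", "76")
  genes <- data.frame(gene_id = "g1",
                      sequence = paste(rep("A", 8), collapse = ""),
                      isotype = "Gly", anticodon = "AAA",
                      sprinzl = paste(labels, collapse = ","),
                      stringsAsFactors = FALSE)
  toy <- write_toy_gene_set(dir, genes)
  uniq <- deduplicate(parse_gene_set(toy$fasta, toy$annotation))
  ann <- load_sprinzl(toy$annotation, uniq)

  # mutual inverses on every annotated label
  for (k in seq_along(labels)) {
    expect_equal(sprinzl_of(ann, "g1", k - 1L), labels[k])
    expect_equal(linear_of(ann, "g1", labels[k]), k - 1L)
  }
  expect_equal(sprinzl_of(ann, "g1", -1L), "not-in-body")
  expect_equal(sprinzl_of(ann, "g1", 8L), "not-in-body")
  expect_true(is.na(linear_of(ann, "g1", "58")))   # absent label, no error
  expect_error(sprinzl_of(ann, "nope", 0L), "unknown seq_id")
})

test_that("Sprinzl inverse property holds on randomised label tables", {
  dir <- withr::local_tempdir()
  set.seed(3)
  n <- 40L
  labels <- sample(c(as.character(1:60), paste0("e", 1:20),
                     paste0(17, letters[1:6])), n)
  genes <- data.frame(gene_id = "gr",
                      sequence = paste(sample(c("A", "C", "G", "T"), n,
                                              replace = TRUE), collapse = ""),
                      isotype = "Ser", anticodon = "GCT",
                      sprinzl = paste(labels, collapse = ","),
                      stringsAsFactors = FALSE)
  toy <- write_toy_gene_set(dir, genes)
  uniq <- deduplicate(parse_gene_set(toy$fasta, toy$annotation))
  ann <- load_sprinzl(toy$annotation, uniq)
  pos <- 0:(n - 1L)
  expect_equal(linear_of(ann, "gr", sprinzl_of(ann, "gr", pos)), pos)
})
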