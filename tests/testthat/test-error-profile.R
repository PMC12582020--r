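pileup_row <- function(ref, A = 0, C = 0, G = 0, T = 0, del = 0, ins = 0) {
  df <- data.frame(seq_id = "s", pos = 0L, ref_base = ref, A = A, C = C,
                   G = G, T = T, del = del, ins = ins,
                   stringsAsFactors = FALSE)
  df$total_events <- A + C + G + T + del
  df
}

test_that("relative error counts mismatches and deletions, never insertions", {
  p <- pileup_row("A", A = 80, C = 10, del = 10, ins = 50)
  expect_equal(relative_error(p), 0.2)
  expect_equal(ref_base_fraction(p), 0.8)
  expect_equal(relative_error(pileup_row("G", G = 100)), 0)
  expect_equal(relative_error(pileup_row("G", del = 40)), 1)
  expect_equal(ref_base_fraction(pileup_row("C", C = 90, A = 5, del = 5)),
               0.9)
  expect_true(is.na(relative_error(pileup_row("A"))))
})

test_that("relative error and reference-base fraction are complementary", {
  p <- random_pileups(2000, seed = 17)
  p <- p[p$total_events > 0, ]
  expect_equal(relative_error(p) + ref_base_fraction(p),
               rep(1, nrow(p)))
})

test_that("pileups reflect planted base composition and quality filters", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fasta")
  writeLines(c(">t1", "ACGTACGTAC"), fa)
  sam <- file.path(dir, "reads.sam")
  # 70 perfect reads, 30 with a C>T mismatch at position 2 (0-based 1),
  # and one low-quality read that must not be counted
  recs <- c(
    vapply(1:70, function(i) sam_record(paste0("p", i), 0, "t1", 1, 30,
                                        "10M", "ACGTACGTAC",
                                        "IIIIIIIIII", "AS:i:10"), ""),
    vapply(1:30, function(i) sam_record(paste0("m", i), 0, "t1", 1, 30,
                                        "10M", "ATGTACGTAC",
                                        "IIIIIIIIII", "AS:i:8"), ""),
    sam_record("low", 0, "t1", 1, 30, "10M", "AAAAAAAAAA",
               paste(rep("\"", 10), collapse = ""), "AS:i:0"))  # Phred 1
  write_sam(sam, c(t1 = 10L), recs)
  bam <- sam_to_bam(sam)
  pu <- build_pileup(bam, fa, min_baseq = 2)
  p2 <- pu[pu$pos == 1L, ]
  expect_equal(p2$ref_base, "C")
  expect_equal(p2$C, 70L)
  expect_equal(p2$T, 30L)
  expect_equal(p2$total_events, 100L)            # low-qual base excluded
  expect_equal(relative_error(p2), 0.3)
  p1 <- pu[pu$pos == 0L, ]
  expect_equal(relative_error(p1), 0)
})

test_that("deletions are counted at each deleted reference position", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fasta")
  writeLines(c(">t1", "ACGTACGTAC"), fa)
  sam <- file.path(dir, "reads.sam")
  recs <- c(
    vapply(1:8, function(i) sam_record(paste0("f", i), 0, "t1", 1, 30,
                                       "10M", "ACGTACGTAC", "IIIIIIIIII",
                                       "AS:i:10"), ""),
    vapply(1:2, function(i) sam_record(paste0("d", i), 0, "t1", 1, 30,
                                       "4M2D4M", "ACGTGTAC", "IIIIIIII",
                                       "AS:i:4"), ""))
  write_sam(sam, c(t1 = 10L), recs)
  pu <- build_pileup(sam_to_bam(sam), fa)
  expect_equal(pu$del[pu$pos == 4L], 2L)
  expect_equal(pu$del[pu$pos == 5L], 2L)
  expect_equal(relative_error(pu[pu$pos == 4L, ]), 0.2)
})

test_that("the minimum-event filter removes shallow positions everywhere", {
  p <- random_pileups(500, seed = 23)
  prof <- error_profile(p, min_events = 80)
  expect_true(all(prof$total_events >= 80))
  expect_true(all(c("relative_error", "ref_base_fraction") %in% names(prof)))
})

test_that("condition log2 ratios follow the mean-error ratio", {
  mk <- function(err, ids = seq_along(err)) {
    df <- pileup_row("A", A = 100)[rep(1, length(err)), ]
    df$pos <- ids - 1L
    df$relative_error <- err
    df$ref_base_fraction <- 1 - err
    df
  }
  out <- condition_log2_ratio(list(mk(c(0.4, 0.2))), list(mk(c(0.1, 0.2))))
  expect_equal(out$log2_ratio, c(2, 0))
  # zero control mean yields the infinity sentinel unless a pseudo-count is on
  z <- condition_log2_ratio(list(mk(0.4)), list(mk(0)))
  expect_equal(z$log2_ratio, Inf)
  zp <- condition_log2_ratio(list(mk(0.4)), list(mk(0)), pseudocount = 0.01)
  expect_true(is.finite(zp$log2_ratio))
  # replicate means: (0.3+0.5)/2 over (0.1+0.3)/2
  r <- condition_log2_ratio(list(mk(0.3), mk(0.5)), list(mk(0.1), mk(0.3)))
  expect_equal(r$log2_ratio, 1)
  # positions missing from any replicate are dropped (intersection rule)
  i <- condition_log2_ratio(list(mk(c(0.4, 0.2), 1:2)), list(mk(0.1, 1)))
  expect_equal(nrow(i), 1L)
})

test_that("identical groups give t = 0 and p = 1 in the global test", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  uniq <- deduplicate(parse_gene_set(toy$fasta, toy$annotation))
  ann <- load_sprinzl(toy$annotation, uniq)
  mk <- function(err) data.frame(
    seq_id = rep(uniq$seq_id, each = 2), pos = rep(0:1, 3),
    relative_error = err, stringsAsFactors = FALSE)
  same <- mk(rep(0.25, 6))
  res <- global_position_test(list(same), list(same), ann)
  expect_equal(res$t, rep(0, 2))
  expect_equal(res$p, rep(1, 2))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("site error report averages replicates per Sprinzl label", {
  dir <- withr::local_tempdir()
  toy <- write_toy_gene_set(dir)
  uniq <- deduplicate(parse_gene_set(toy$fasta, toy$annotation))
  ann <- load_sprinzl(toy$annotation, uniq)
  mk <- function(err) data.frame(seq_id = "gA1", pos = 6L,
                                 relative_error = err,
                                 stringsAsFactors = FALSE)
  rep2 <- site_error_report(list(high = list(mk(0.2), mk(0.4))),
                            "gA1", "7", ann)
  expect_equal(rep2$mean_error, 0.3)
  expect_equal(rep2$sd_error, sd(c(0.2, 0.4)))
  rep1 <- site_error_report(list(high = list(mk(0.2))), "gA1", "7", ann)
  expect_true(is.na(rep1$sd_error))
  absent <- site_error_report(list(high = list(mk(0.2))), "gA1", "e9", ann)
  expect_true(is.na(absent$mean_error))
  expect_equal(absent$n_replicates, 0L)
})
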