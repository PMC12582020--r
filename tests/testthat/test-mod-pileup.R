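test_that("bedMethyl files parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "five.bedmethyl")
  rec <- rbind(bed_record(start = 1L, n_mod = 0L),
               bed_record(start = 5L, n_mod = 50L),
               bed_record(start = 9L, code = "17802", n_mod = 180L),
               bed_record(start = 12L, code = "a", n_mod = 200L),
               bed_record(start = 20L, strand = "-"))
  write_bedmethyl(rec, path)
  got <- parse_bedmethyl(path, sample = "s1")
  expect_equal(nrow(got), 5L)
  expect_equal(got$fraction_modified,
               rec$n_mod / rec$n_valid)
  expect_equal(got$mod_type[3], "pseU")
  expect_equal(got$canonical_base, c("C", "C", "T", "A", "C"))
  # round trip: write the parsed records and parse again
  path2 <- file.path(dir, "again.bedmethyl")
  write_bedmethyl(got, path2)
  expect_equal(parse_bedmethyl(path2, sample = "s1"), got)
})

test_that("malformed bedMethyl lines fail with their line number", {
  dir <- withr::local_tempdir()
  ok <- bed_record()
  bad <- bed_record(start = 9L)
  bad$n_mod <- 300L  # exceeds n_valid
  path <- file.path(dir, "bad.bedmethyl")
  write_bedmethyl(rbind(ok, bad), path)
  expect_error(parse_bedmethyl(path), "line 2")

  trunc <- file.path(dir, "trunc.bedmethyl")
  writeLines("t1\t5\t6\tm", trunc)
  expect_error(parse_bedmethyl(trunc), "18 columns")

  unk <- file.path(dir, "unknown.bedmethyl")
  rec <- rbind(ok, bed_record(start = 7L))
  rec$mod_code[2] <- "z"
  write_bedmethyl(rec, unk)
  expect_warning(got <- parse_bedmethyl(unk), "unknown modification code")
  expect_equal(nrow(got), 1L)
})

test_that("record filtering enforces strand, reference match and depth", {
  ref <- c(t1 = "AACCTTTTGG")
  recs <- rbind(
    bed_record(start = 2L),                      # C at ref pos 2: kept
    bed_record(start = 2L, n_valid = 99L, n_mod = 10L),  # shallow
    bed_record(start = 2L, strand = "-"),        # wrong strand
    bed_record(start = 4L),                      # m5C where reference is T
    bed_record(start = 5L, code = "17802", n_mod = 80L))  # pseU on T: kept
  filt <- filter_mod_records(recs, ref)
  expect_equal(nrow(filt), 2L)
  expect_equal(filt$start, c(2L, 5L))
  # idempotent and order-independent
  expect_equal(filter_mod_records(filt, ref), filt)
  shuffled <- recs[c(4, 2, 5, 1, 3), ]
  refilt <- filter_mod_records(shuffled, ref)
  expect_equal(refilt[order(refilt$start), ]$n_valid,
               filt[order(filt$start), ]$n_valid)
  expect_error(filter_mod_records(bed_record(seq_id = "nope"), ref),
               "absent from reference")
})

test_that("site averaging is an unweighted mean over contributing samples", {
  recs <- rbind(cbind(bed_record(n_mod = 40L), sample = "u1"),
                cbind(bed_record(n_mod = 80L), sample = "u2"),
                cbind(bed_record(n_mod = 200L), sample = "treated"))
  recs$fraction_modified <- recs$n_mod / recs$n_valid
  sites <- average_sites(recs, samples = c("u1", "u2"))
  expect_equal(sites$mean_probability, 0.3)
  expect_equal(sites$n_samples, 2L)
  one <- average_sites(recs, samples = "u1")
  expect_equal(one$mean_probability, 0.2)
})

test_that("probability cutoffs are strict and threshold sets nest", {
  sites <- data.frame(seq_id = "t1", start = 1:4, mod_code = "m",
                      mod_type = "m5C",
                      mean_probability = c(0.10, 0.101, 0.25, 0),
                      n_samples = 2L, stringsAsFactors = FALSE)
  at10 <- threshold_sites(sites, 10)
  expect_equal(at10$start, c(2L, 3L))      # exactly 10% excluded
  at0 <- threshold_sites(sites, 0)
  expect_equal(at0$start, 1:3)             # any modified call passes 0%
  at20 <- threshold_sites(sites, 20)
  expect_true(all(at20$start %in% at10$start))
  expect_true(all(at10$start %in% at0$start))
})

test_that("orthogonal comparison counts shared and exclusive site keys", {
  nano <- data.frame(trna = c("Gly-GCC", "Gly-GCC", "Asp-GTC"),
                     label = c("48", "49", "38"), stringsAsFactors = FALSE)
  ortho <- data.frame(trna = c("Gly-GCC", "Asp-GTC", "Cys-GCA"),
                      label = c("49", "38", "72"),
                      rate = c(90, 45, 12), stringsAsFactors = FALSE)
  cmp <- compare_orthogonal(nano, ortho)
  expect_equal(cmp$n_shared, 2L)
  expect_equal(cmp$n_left_only, 1L)
  expect_equal(cmp$n_right_only, 1L)
  expect_equal(nrow(nano) , cmp$n_shared + cmp$n_left_only)
  expect_equal(length(unique(paste(ortho$trna, ortho$label))),
               cmp$n_shared + cmp$n_right_only)

  disjoint <- compare_orthogonal(nano, data.frame(trna = "His-GTG",
                                                  label = "72", rate = 50))
  expect_equal(disjoint$n_shared, 0L)

  # the orthogonal pre-filter is strict, and unmappable rows are reported
  strict <- compare_orthogonal(nano, ortho, min_orthogonal_rate = 12,
                               known_trnas = c("Gly-GCC", "Asp-GTC"))
  expect_equal(strict$n_right_only, 0L)    # Cys dropped: rate 12 not > 12
  filt <- compare_orthogonal(nano, ortho, min_orthogonal_rate = 10,
                             known_trnas = c("Gly-GCC", "Asp-GTC"))
  expect_equal(nrow(filt$unmapped), 1L)
  expect_equal(filt$unmapped$trna, "Cys-GCA")
})

test_that("annotated sites roll up to anticodon level by maximum", {
  sites <- data.frame(
    seq_id = c("g1", "g2", "g3"), start = 11L, mod_code = "m",
    mod_type = "m5C", mean_probability = c(0.2, 0.5, 0.4), n_samples = 2L,
    label = "48", anticodon = c("Gly-GCC", "Gly-GCC", "Asp-GTC"),
    stringsAsFactors = FALSE)
  roll <- rollup_anticodon(sites)
  expect_equal(roll$mean_probability[roll$anticodon == "Gly-GCC"], 0.5)
  expect_equal(roll$n_isodecoders[roll$anticodon == "Gly-GCC"], 2L)
  expect_equal(nrow(roll), 2L)
})
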