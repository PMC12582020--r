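# Anticodon-level quantification: per-MAPQ-bin QC counts, the expression
# matrix, fixed-sum normalization and mapping QC fractions.

#' Count reads per (anticodon, MOD-MAPQ bin, category)
#'
#' Only forward-strand reads whose mean base-call quality exceeds
#' `min_read_qual` are counted. `same_target` / `same_codon` / `ambiguous`
#' reads all sit in the MAPQ-0 bin under their own category, which is what
#' makes the per-bin table usable for quality control.
#'
#' @param assignments Assignments table from [process_alignments()].
#' @param min_read_qual Strict lower bound on mean base-call quality
#'   (default 4.0, the pipeline's standard read-quality filter).
#' @return data.frame `anticodon`, `mod_mapq`, `category`, `count`.
#'   Ambiguous reads carry anticodon `"*"`.
#' @export
count_per_mapq_bin <- function(assignments, min_read_qual = 4.0) {
  keep <- assignments$category %in%
    c("unique", "same_target", "same_codon", "ambiguous") &
    assignments$strand %in% "+" &
    !is.na(assignments$mean_base_quality) &
    assignments$mean_base_quality > min_read_qual
  a <- assignments[keep, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(anticodon = character(), mod_mapq = integer(),
                      category = character(), count = integer(),
                      stringsAsFactors = FALSE))
  ac <- ifelse(is.na(a$anticodon), "*", a$anticodon)
  key <- paste(ac, a$mod_mapq, a$category, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    anticodon = vapply(parts, `[[`, "", 1L),
    mod_mapq = as.integer(vapply(parts, `[[`, "", 2L)),
    category = vapply(parts, `[[`, "", 3L),
    count = as.integer(tab),
    stringsAsFactors = FALSE)
  out <- out[order(out$anticodon, out$mod_mapq, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the anticodon x sample expression matrix
#'
#' Per sample, the count for an anticodon is the sum of its MAPQ > 0
#' (unique) bins plus its MAPQ-0 `same_codon` bin; MAPQ-0 `same_target`
#' reads are included by default since they identify a single tRNA (set
#' `include_same_target = FALSE` for the strict same-codon-only reading).
#' Ambiguous reads are never counted.
#'
#' @param bins_by_sample Named list of per-bin tables
#'   ([count_per_mapq_bin()]), one per sample.
#' @param include_same_target Include MAPQ-0 `same_target` reads
#'   (default TRUE).
#' @return Integer matrix, rows = anticodons, columns = samples.
#' @export
expression_matrix <- function(bins_by_sample, include_same_target = TRUE) {
  stopifnot(length(names(bins_by_sample)) == length(bins_by_sample))
  counted_one <- function(bins) {
    ok <- (bins$category == "unique" & bins$mod_mapq > 0L) |
      (bins$category == "same_codon" & bins$mod_mapq == 0L) |
      (include_same_target & bins$category == "same_target" &
         bins$mod_mapq == 0L)
    b <- bins[ok, , drop = FALSE]
    tapply(b$count, b$anticodon, sum)
  }
  per_sample <- lapply(bins_by_sample, counted_one)
  # rows cover every anticodon observed in any bin (zero rows retained for
  # anticodons whose reads were all filtered), never the ambiguous "*"
  anticodons <- sort(setdiff(unique(unlist(
    lapply(bins_by_sample, `[[`, "anticodon"))), "*"))
  mat <- matrix(0L, nrow = length(anticodons), ncol = length(per_sample),
                dimnames = list(anticodons, names(bins_by_sample)))
  for (s in names(per_sample)) {
    v <- per_sample[[s]]
    if (length(v)) mat[names(v), s] <- as.integer(v)
  }
  mat
}

#' Normalize each sample column to a fixed sum
#'
#' Columns are rescaled so every sample sums to `total` (1000 by default),
#' giving scale-free relative anticodon abundances comparable across runs
#' of different depth.
#'
#' @param mat Count matrix from [expression_matrix()].
#' @param total Target column sum (default 1000).
#' @return Numeric matrix with each column summing to `total`.
#' @export
normalize_fixed_sum <- function(mat, total = 1000) {
  cs <- colSums(mat)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero count column for sample '",
         colnames(mat)[zero][1L], "'")
  sweep(mat, 2L, cs / total, "/")
}

#' Mapping QC fractions per sample
#'
#' Proper = forward-strand mapped reads; antisense = reverse-strand mapped
#' reads (a proxy for mis-mapping). Fractions are over mapped reads only and
#' are NA when nothing mapped.
#'
#' @param assignments Assignments table from [process_alignments()].
#' @return One-row data.frame: `n_mapped`, `n_unmapped`, `fraction_proper`,
#'   `fraction_antisense`.
#' @export
mapping_qc <- function(assignments) {
  mapped <- assignments$category != "unmapped"
  n_mapped <- sum(mapped)
  anti <- sum(assignments$category == "antisense")
  data.frame(
    n_mapped = n_mapped,
    n_unmapped = sum(!mapped),
    fraction_proper = if (n_mapped) (n_mapped - anti) / n_mapped else NA_real_,
    fraction_antisense = if (n_mapped) anti / n_mapped else NA_real_)
}
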