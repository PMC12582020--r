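# Base-calling-error statistics. Modified ribonucleotides perturb the
# nanopore current and induce systematic miscalls (mismatches, deletions) at
# and around their positions; per-position error statistics therefore flag
# candidate modification sites. Pileups are computed with Rsamtools on the
# MOD-MAPQ-recalibrated BAM.

#' Per-position base pileup over the reference
#'
#' Forward-strand pileup of base, deletion and insertion counts per
#' reference position, using reads with a minimum (recalibrated) mapping
#' quality, a minimum base-call quality and a per-position depth cap.
#' `total_events` counts matches, mismatches and deletions; insertions are
#' tracked but excluded from the event total.
#'
#' @param bam Path to a (sorted, indexed) BAM with recalibrated MAPQ.
#' @param reference_fasta The reference FASTA the BAM was aligned to.
#' @param min_mapq Minimum mapping quality (default 1).
#' @param min_baseq Minimum base-call quality (default 2).
#' @param max_depth Per-position depth cap (default 50000).
#' @param padded Optional padded-reference table
#'   ([build_padded_reference()]); when given, `body_pos` (0-based position
#'   within the tRNA body) and `in_body` columns are added so adapter-pad
#'   positions can be excluded downstream.
#' @return data.frame: `seq_id`, `pos` (0-based reference coordinate),
#'   `ref_base`, counts `A`,`C`,`G`,`T`,`del`,`ins`, `total_events`, and
#'   optionally `body_pos`, `in_body`.
#' @export
build_pileup <- function(bam, reference_fasta, min_mapq = 1L, min_baseq = 2L,
                         max_depth = 50000L, padded = NULL) {
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  pp <- Rsamtools::PileupParam(
    max_depth = max_depth, min_base_quality = min_baseq, min_mapq = min_mapq,
    min_nucleotide_depth = 1L, distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE, ignore_query_Ns = FALSE,
    include_deletions = TRUE, include_insertions = TRUE)
  res <- Rsamtools::pileup(bam, pileupParam = pp)
  bad <- setdiff(unique(as.character(res$seqnames)), names(ref))
  if (length(bad))
    stop("BAM contig '", bad[1L], "' absent from reference FASTA")
  res <- res[res$strand == "+", , drop = FALSE]
  res$seq_id <- as.character(res$seqnames)
  res$nuc <- as.character(res$nucleotide)

  keys <- unique(res[, c("seq_id", "pos")])
  keys <- keys[order(keys$seq_id, keys$pos), , drop = FALSE]
  kid <- match(paste(res$seq_id, res$pos),
               paste(keys$seq_id, keys$pos))
  cols <- c("A", "C", "G", "T", "-", "+")
  wide <- matrix(0L, nrow = nrow(keys), ncol = length(cols),
                 dimnames = list(NULL, cols))
  jd <- match(res$nuc, cols)
  ok <- !is.na(jd)
  # one row per (seq, pos, nucleotide) after the strand filter, so plain
  # assignment (not accumulation) is safe
  wide[cbind(kid[ok], jd[ok])] <- res$count[ok]

  pos0 <- keys$pos - 1L
  ref_base <- vapply(seq_len(nrow(keys)), function(i)
    substr(as.character(ref[[keys$seq_id[i]]]), keys$pos[i], keys$pos[i]),
    character(1L))
  out <- data.frame(
    seq_id = keys$seq_id, pos = pos0, ref_base = ref_base,
    A = wide[, "A"], C = wide[, "C"], G = wide[, "G"], T = wide[, "T"],
    del = wide[, "-"], ins = wide[, "+"], stringsAsFactors = FALSE)
  out$total_events <- out$A + out$C + out$G + out$T + out$del
  if (!is.null(padded)) {
    m <- match(out$seq_id, padded$seq_id)
    out$body_pos <- out$pos - padded$body_offset[m]
    out$in_body <- out$body_pos >= 0L & out$body_pos < padded$body_length[m]
  }
  rownames(out) <- NULL
  out
}

ref_base_counts <- function(pileup) {
  m <- as.matrix(pileup[, c("A", "C", "G", "T")])
  j <- match(pileup$ref_base, colnames(m))
  rc <- rep(0L, nrow(pileup))
  ok <- !is.na(j)
  rc[ok] <- m[cbind(which(ok), j[ok])]
  rc
}

#' Relative base-calling error per position
#'
#' Incorrect basecalls (mismatches plus deletions) divided by the total
#' count of sequencing events (match/mismatch/deletion). Insertions are
#' excluded from both numerator and denominator.
#'
#' @param pileup Pileup table from [build_pileup()].
#' @return Numeric vector in \[0,1\]; NA where `total_events` is 0.
#' @export
relative_error <- function(pileup) {
  rc <- ref_base_counts(pileup)
  ifelse(pileup$total_events > 0,
         (pileup$total_events - rc) / pileup$total_events, NA_real_)
}

#' Reference-base fraction per position
#'
#' Count for the reference base divided by the sum of canonical-base and
#' deletion counts. Complementary to [relative_error()]:
#' `ref_base_fraction + relative_error == 1` wherever defined.
#'
#' @inheritParams relative_error
#' @return Numeric vector in \[0,1\]; NA where `total_events` is 0.
#' @export
ref_base_fraction <- function(pileup) {
  rc <- ref_base_counts(pileup)
  ifelse(pileup$total_events > 0, rc / pileup$total_events, NA_real_)
}

#' Per-position error profile
#'
#' Adds `relative_error` and `ref_base_fraction` to a pileup and applies the
#' minimum-event filter: positions with fewer than `min_events` events
#' (default 80) never reach downstream tables. When the pileup carries body
#' annotation, adapter-pad positions are dropped as well.
#'
#' @inheritParams relative_error
#' @param min_events Minimum `total_events` per position (default 80).
#' @param body_only Drop positions outside the tRNA body when the pileup has
#'   an `in_body` column (default TRUE).
#' @return Filtered pileup with `relative_error`, `ref_base_fraction`.
#' @export
error_profile <- function(pileup, min_events = 80L, body_only = TRUE) {
  out <- pileup
  out$relative_error <- relative_error(out)
  out$ref_base_fraction <- ref_base_fraction(out)
  if (body_only && "in_body" %in% names(out))
    out <- out[out$in_body, , drop = FALSE]
  out <- out[out$total_events >= min_events, , drop = FALSE]
  rownames(out) <- NULL
  out
}

profile_key <- function(df) paste(df$seq_id, df$pos)

#' Condition-versus-control log2 error ratios
#'
#' For every position passing the minimum-event filter in *all* replicates
#' of both conditions (intersection, avoiding replicate-composition
#' artifacts), computes `log2(mean_exp / mean_ctrl)` of the replicate-mean
#' relative errors. A zero control mean yields `Inf` (sentinel) unless a
#' pseudo-count is supplied.
#'
#' @param exp_profiles,ctrl_profiles Lists of replicate error profiles
#'   ([error_profile()]) for the experimental and control conditions.
#' @param pseudocount Added to both means before the ratio (default 0, off).
#' @return data.frame `seq_id`, `pos`, (`body_pos` when available),
#'   `mean_exp`, `mean_ctrl`, `log2_ratio`.
#' @export
condition_log2_ratio <- function(exp_profiles, ctrl_profiles,
                                 pseudocount = 0) {
  all_profiles <- c(exp_profiles, ctrl_profiles)
  keys <- Reduce(intersect, lapply(all_profiles, profile_key))
  if (!length(keys))
    return(data.frame(seq_id = character(), pos = integer(),
                      mean_exp = numeric(), mean_ctrl = numeric(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  cond_mean <- function(profiles) {
    vals <- vapply(profiles, function(df)
      df$relative_error[match(keys, profile_key(df))], numeric(length(keys)))
    rowMeans(matrix(vals, nrow = length(keys)))
  }
  first <- all_profiles[[1L]]
  m <- match(keys, profile_key(first))
  out <- data.frame(seq_id = first$seq_id[m], pos = first$pos[m],
                    stringsAsFactors = FALSE)
  if ("body_pos" %in% names(first)) out$body_pos <- first$body_pos[m]
  out$mean_exp <- cond_mean(exp_profiles)
  out$mean_ctrl <- cond_mean(ctrl_profiles)
  out$log2_ratio <- log2((out$mean_exp + pseudocount) /
                           (out$mean_ctrl + pseudocount))
  out
}

label_positions <- function(sprinzl, seq_ids, positions) {
  out <- rep(NA_character_, length(seq_ids))
  for (sid in unique(seq_ids)) {
    i <- which(seq_ids == sid)
    out[i] <- sprinzl_of(sprinzl, sid, positions[i])
  }
  out
}

welch_or_degenerate <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Global per-Sprinzl-position error test
#'
#' For every Sprinzl label, pools the per-position relative errors of all
#' tRNA sequences (across replicates) within each condition and runs a
#' two-sample t-test (Welch by default) experimental vs control; p-values
#' are adjusted across labels with the Benjamini-Hochberg procedure. Labels
#' with fewer than `min_obs` observations in either group are skipped with
#' a message.
#'
#' @inheritParams condition_log2_ratio
#' @param sprinzl A `sprinzl_annotation` ([load_sprinzl()]).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @param min_obs Minimum observations per group per label (default 2).
#' @return data.frame `label`, `n_exp`, `n_ctrl`, `mean_exp`, `mean_ctrl`,
#'   `t`, `p`, `p_adj`, ordered by `p`.
#' @export
global_position_test <- function(exp_profiles, ctrl_profiles, sprinzl,
                                 var_equal = FALSE, min_obs = 2L) {
  collect <- function(profiles) {
    do.call(rbind, lapply(profiles, function(df) {
      bp <- if ("body_pos" %in% names(df)) df$body_pos else df$pos
      data.frame(label = label_positions(sprinzl, df$seq_id, bp),
                 err = df$relative_error, stringsAsFactors = FALSE)
    }))
  }
  ex <- collect(exp_profiles)
  ct <- collect(ctrl_profiles)
  drop_lab <- function(d)
    d[!is.na(d$label) & d$label != "not-in-body", , drop = FALSE]
  ex <- drop_lab(ex); ct <- drop_lab(ct)
  labels <- intersect(unique(ex$label), unique(ct$label))
  rows <- lapply(labels, function(lab) {
    x <- ex$err[ex$label == lab]
    y <- ct$err[ct$label == lab]
    if (length(x) < min_obs || length(y) < min_obs) {
      message("Sprinzl label '", lab, "' skipped (insufficient observations)")
      return(NULL)
    }
    tp <- welch_or_degenerate(x, y, var_equal)
    data.frame(label = lab, n_exp = length(x), n_ctrl = length(y),
               mean_exp = mean(x), mean_ctrl = mean(y),
               t = tp[["t"]], p = tp[["p"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(label = character(), n_exp = integer(),
                      n_ctrl = integer(), mean_exp = numeric(),
                      mean_ctrl = numeric(), t = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate mean +/- sd of relative error at selected Sprinzl positions
#'
#' Reports, per condition and requested label, the across-replicate mean and
#' standard deviation of the relative error on one tRNA (e.g. positions
#' 36-38 of Phe-GAA, the wybutosine neighbourhood). Labels the sequence
#' lacks produce an absent-value row rather than an error; with a single
#' replicate the sd is NA.
#'
#' @param profiles_by_condition Named list: condition -> list of replicate
#'   error profiles.
#' @param seq_id Unique-sequence id to report on.
#' @param labels Character vector of Sprinzl labels.
#' @param sprinzl A `sprinzl_annotation`.
#' @return data.frame `condition`, `label`, `n_replicates`, `mean_error`,
#'   `sd_error`.
#' @export
site_error_report <- function(profiles_by_condition, seq_id, labels,
                              sprinzl) {
  rows <- list()
  for (cond in names(profiles_by_condition)) {
    reps <- profiles_by_condition[[cond]]
    for (lab in labels) {
      pos <- linear_of(sprinzl, seq_id, lab)
      vals <- if (is.na(pos)) numeric() else
        unlist(lapply(reps, function(df) {
          bp <- if ("body_pos" %in% names(df)) df$body_pos else df$pos
          df$relative_error[df$seq_id == seq_id & bp == pos]
        }))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, label = lab, n_replicates = length(vals),
        mean_error = if (length(vals)) mean(vals) else NA_real_,
        sd_error = if (length(vals) >= 2L) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
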