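# bedMethyl (modkit pileup dialect) modification analysis: parse, filter,
# average per-site modification probabilities across samples, threshold, and
# compare site sets against orthogonal chemical-sequencing tables
# (bisulfite-based m5C, cyclization-based pseudouridine).

MOD_CODES <- c(m = "m5C", a = "m6A", `17802` = "pseU")
MOD_CANONICAL <- c(m = "C", a = "A", `17802` = "T")

#' Parse a modkit-dialect bedMethyl file
#'
#' Expects the 18-column modkit pileup layout: chrom, start, end, mod code,
#' score (= N_valid), strand, thickStart, thickEnd, color, N_valid,
#' percent_modified, N_mod, N_canonical, N_other_mod, N_delete, N_fail,
#' N_diff, N_nocall. Records with an unknown modification code are skipped
#' with a warning; malformed lines (wrong column count, counts that
#' contradict each other or the printed percent) are hard errors naming the
#' line.
#'
#' @param path bedMethyl file path.
#' @param sample Optional sample id attached to every record.
#' @return data.frame: `seq_id`, `start` (0-based), `strand`, `mod_code`,
#'   `mod_type`, `canonical_base`, `n_valid`, `n_mod`, `n_canonical`,
#'   `fraction_modified` (fraction in \[0,1\], recomputed from counts),
#'   `sample`.
#' @export
parse_bedmethyl <- function(path, sample = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 18L)
  if (length(bad))
    stop("malformed bedMethyl line ", bad[1L], " in '", path,
         "': expected 18 columns, found ", lengths(parts)[bad[1L]])
  get <- function(k) vapply(parts, `[[`, character(1L), k)
  code <- get(4L)
  known <- code %in% names(MOD_CODES)
  if (any(!known))
    warning(sum(!known), " record(s) with unknown modification code ",
            "skipped (e.g. '", code[!known][1L], "')")
  num <- function(k) suppressWarnings(as.numeric(get(k)))
  int <- function(k) suppressWarnings(as.integer(get(k)))
  out <- data.frame(
    seq_id = get(1L), start = int(2L), strand = get(6L),
    mod_code = code,
    mod_type = unname(MOD_CODES[code]),
    canonical_base = unname(MOD_CANONICAL[code]),
    n_valid = int(10L), percent = num(11L), n_mod = int(12L),
    n_canonical = int(13L), stringsAsFactors = FALSE)
  broken <- which(is.na(out$start) | is.na(out$n_valid) | is.na(out$n_mod) |
                    is.na(out$percent))
  if (length(broken))
    stop("malformed bedMethyl line ", broken[1L], " in '", path,
         "': non-numeric coordinate or count field")
  over <- which(out$n_mod > out$n_valid)
  if (length(over))
    stop("malformed bedMethyl line ", over[1L], " in '", path,
         "': N_mod (", out$n_mod[over[1L]], ") exceeds N_valid (",
         out$n_valid[over[1L]], ")")
  frac <- ifelse(out$n_valid > 0, out$n_mod / out$n_valid, 0)
  # our writer prints percent at 1e-6; tolerate modkit's 2-decimal rounding
  off <- which(abs(out$percent / 100 - frac) > 0.005 + 1e-9)
  if (length(off))
    stop("malformed bedMethyl line ", off[1L], " in '", path,
         "': percent_modified inconsistent with N_mod/N_valid")
  out$fraction_modified <- frac
  out$percent <- NULL
  out$sample <- sample
  out <- out[known, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write records as modkit-dialect bedMethyl
#'
#' Inverse of [parse_bedmethyl()] for the columns the package models; the
#' remaining count columns (other-mod, delete, fail, diff, nocall) are
#' written as 0. The modified percent is printed at 6 decimal places so a
#' write/parse round trip is an identity.
#'
#' @param records data.frame in the layout returned by [parse_bedmethyl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%s\t%d\t%d\t0\t0\t0\t0\t0",
    records$seq_id, records$start, records$start + 1L, records$mod_code,
    records$n_valid, records$strand, records$start, records$start + 1L,
    records$n_valid,
    sprintf("%.6f", 100 * records$n_mod / pmax(records$n_valid, 1L)),
    records$n_mod, records$n_canonical)
  writeLines(lines, path)
  invisible(path)
}

#' Filter modification-pileup records
#'
#' Keeps plus-strand records whose canonical (unmodified) base matches the
#' reference base at the call position and which have at least
#' `min_valid_calls` valid calls (confidently modified or unmodified;
#' default 100). Idempotent and order-independent.
#'
#' @param records Records from [parse_bedmethyl()].
#' @param reference Named character vector (or `DNAStringSet`) of reference
#'   sequences keyed by `seq_id`, in the coordinate space of the pileup.
#' @param min_valid_calls Minimum valid-call count (default 100).
#' @return The filtered records.
#' @export
filter_mod_records <- function(records, reference, min_valid_calls = 100L) {
  reference <- stats::setNames(as.character(reference), names(reference))
  missing <- setdiff(unique(records$seq_id), names(reference))
  if (length(missing))
    stop("pileup sequence '", missing[1L], "' absent from reference")
  ref_at <- substring(reference[records$seq_id], records$start + 1L,
                      records$start + 1L)
  keep <- records$strand == "+" &
    records$n_valid >= min_valid_calls &
    ref_at == records$canonical_base
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average per-site modification probabilities across samples
#'
#' Unweighted mean of the per-sample modified fraction per
#' (`seq_id`, `start`, `mod_code`); a site absent from a sample (e.g.
#' filtered out there) contributes no term. The sample set is typically the
#' untreated wild-type samples, supplied explicitly.
#'
#' @param records Filtered records carrying a `sample` column.
#' @param samples Optional character vector restricting which samples enter
#'   the average (default: all samples present).
#' @return data.frame `seq_id`, `start`, `mod_code`, `mod_type`,
#'   `mean_probability` (fraction in \[0,1\]), `n_samples`.
#' @export
average_sites <- function(records, samples = NULL) {
  if (!is.null(samples))
    records <- records[records$sample %in% samples, , drop = FALSE]
  key <- paste(records$seq_id, records$start, records$mod_code, sep = "\r")
  means <- tapply(records$fraction_modified, key, mean)
  ns <- tapply(records$fraction_modified, key, length)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  out <- data.frame(
    seq_id = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    mod_code = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  out$mod_type <- unname(MOD_CODES[out$mod_code])
  out$mean_probability <- as.numeric(means)
  out$n_samples <- as.integer(ns)
  out <- out[order(out$seq_id, out$start, out$mod_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold averaged sites at a probability cutoff
#'
#' Strict inequality: a site is kept iff its mean modification probability
#' exceeds `cutoff_percent` percent; a site at exactly the cutoff is
#' excluded. Threshold sets are therefore nested: 20% subset of 10% subset
#' of 0%.
#'
#' @param sites Averaged sites from [average_sites()].
#' @param cutoff_percent Cutoff in percent (typically 0, 10 or 20).
#' @return The sites exceeding the cutoff.
#' @export
threshold_sites <- function(sites, cutoff_percent) {
  # compare on the fraction scale: 10/100 and a stored 0.1 share one binary
  # representation, so a site at exactly the cutoff is reliably excluded
  out <- sites[sites$mean_probability > cutoff_percent / 100, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach Sprinzl labels and isoacceptor identity to averaged sites
#'
#' Converts pileup coordinates to body positions via the padded-reference
#' table and looks up the Sprinzl label; sites falling in the adapter pads
#' get label `"not-in-body"`.
#'
#' @param sites Averaged sites from [average_sites()].
#' @param sprinzl A `sprinzl_annotation`.
#' @param padded Padded-reference table ([build_padded_reference()]).
#' @param uniques Unique-sequence table, for the isoacceptor label.
#' @return `sites` with `body_pos`, `label` and `anticodon` columns.
#' @export
annotate_sites <- function(sites, sprinzl, padded, uniques) {
  m <- match(sites$seq_id, padded$seq_id)
  sites$body_pos <- sites$start - padded$body_offset[m]
  sites$label <- label_positions(sprinzl, sites$seq_id, sites$body_pos)
  lut <- anticodon_lookup(uniques)
  sites$anticodon <- unname(lut[sites$seq_id])
  sites
}

#' Roll annotated sites up to anticodon level
#'
#' Site identity for cross-method comparison is (isoacceptor, Sprinzl
#' label, modification); across isodecoders of one anticodon the maximum
#' mean probability is taken. Per-isodecoder rows are what you keep by not
#' calling this.
#'
#' @param sites Annotated sites from [annotate_sites()].
#' @return data.frame `anticodon`, `label`, `mod_code`, `mod_type`,
#'   `mean_probability` (max across isodecoders), `n_isodecoders`.
#' @export
rollup_anticodon <- function(sites) {
  key <- paste(sites$anticodon, sites$label, sites$mod_code, sep = "\r")
  mx <- tapply(sites$mean_probability, key, max)
  ns <- tapply(sites$mean_probability, key, length)
  parts <- strsplit(names(mx), "\r", fixed = TRUE)
  out <- data.frame(
    anticodon = vapply(parts, `[[`, "", 1L),
    label = vapply(parts, `[[`, "", 2L),
    mod_code = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  out$mod_type <- unname(MOD_CODES[out$mod_code])
  out$mean_probability <- as.numeric(mx)
  out$n_isodecoders <- as.integer(ns)
  out <- out[order(out$anticodon, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a nanopore site set against an orthogonal method's site table
#'
#' Sites are keyed on (tRNA identifier, Sprinzl label). The orthogonal
#' table is pre-filtered at `min_orthogonal_rate` percent (0 keeps all
#' reported sites, as for the bisulfite m5C table; 10 keeps high-confidence
#' pseudouridine sites, strict inequality). Orthogonal rows whose tRNA
#' identifier cannot be mapped into `known_trnas` are reported in
#' `unmapped`, never silently dropped.
#'
#' @param nanopore_sites data.frame with columns `trna` and `label` (e.g.
#'   the output of [rollup_anticodon()] with `trna = anticodon`).
#' @param orthogonal data.frame with columns `trna`, `label`, `rate`
#'   (percent).
#' @param min_orthogonal_rate Percent cutoff applied to `orthogonal`
#'   (default 0; strict inequality when > 0).
#' @param known_trnas Optional character vector of valid tRNA identifiers
#'   used to flag unmappable orthogonal rows.
#' @return List of class `site_set_comparison`: `n_shared`, `n_left_only`,
#'   `n_right_only`, `shared`, `left_only`, `right_only` (character keys
#'   `"trna:label"`), `unmapped` (orthogonal rows).
#' @export
compare_orthogonal <- function(nanopore_sites, orthogonal,
                               min_orthogonal_rate = 0,
                               known_trnas = NULL) {
  ortho <- orthogonal
  if (min_orthogonal_rate > 0)
    ortho <- ortho[ortho$rate > min_orthogonal_rate, , drop = FALSE]
  unmapped <- ortho[0, , drop = FALSE]
  if (!is.null(known_trnas)) {
    bad <- !(ortho$trna %in% known_trnas)
    unmapped <- ortho[bad, , drop = FALSE]
    ortho <- ortho[!bad, , drop = FALSE]
  }
  left <- unique(paste(nanopore_sites$trna, nanopore_sites$label, sep = ":"))
  right <- unique(paste(ortho$trna, ortho$label, sep = ":"))
  shared <- intersect(left, right)
  structure(list(
    n_shared = length(shared),
    n_left_only = length(setdiff(left, right)),
    n_right_only = length(setdiff(right, left)),
    shared = sort(shared),
    left_only = sort(setdiff(left, right)),
    right_only = sort(setdiff(right, left)),
    unmapped = unmapped), class = "site_set_comparison")
}

#' @export
print.site_set_comparison <- function(x, ...) {
  cat("Site-set comparison (keys: trna:label)\n")
  cat("  shared:     ", x$n_shared, "\n")
  cat("  left only:  ", x$n_left_only, "\n")
  cat("  right only: ", x$n_right_only, "\n")
  if (nrow(x$unmapped))
    cat("  unmapped orthogonal rows:", nrow(x$unmapped), "\n")
  invisible(x)
}
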