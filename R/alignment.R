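# Mapping-quality recalibration (MOD-MAPQ) and anticodon assignment.
#
# The tRNA reference is short and contains sequences differing by as little
# as one base, so the aligner reports many reads at MAPQ 0 even when the
# primary alignment scores strictly higher than every alternative. MOD-MAPQ
# recovers those reads: when the alignment-score gap between the primary and
# the best alternative hit is positive and exceeds the reported MAPQ, the
# mapping quality is set to that gap. Remaining MAPQ-0 reads are rescued as
# "same target" / "same codon" when all equal-top-score hits agree on one
# reference sequence or one anticodon.

#' Recalibrate a read's mapping quality from alignment-score gaps
#'
#' Computes `d = AS_primary - max(AS_alternatives)`. When `d > 0` and `d`
#' exceeds the originally reported MAPQ, the mapping quality becomes `d`
#' (capped at 60 so downstream tools stay in the conventional MAPQ range);
#' otherwise the original MAPQ is returned. With no scored alternatives the
#' original MAPQ is returned unchanged.
#'
#' @param original_mapq Reported MAPQ (0-60).
#' @param primary_score Alignment score (AS) of the primary hit.
#' @param alt_scores Numeric vector of alternative-hit scores; NAs (hits
#'   lacking a score) are dropped.
#' @param cap Upper bound on the result (default 60).
#' @return Integer MOD-MAPQ.
#' @export
recalibrate_mapq <- function(original_mapq, primary_score,
                             alt_scores = numeric(), cap = 60L) {
  alt_scores <- alt_scores[!is.na(alt_scores)]
  out <- original_mapq
  if (length(alt_scores) && !is.na(primary_score)) {
    d <- primary_score - max(alt_scores)
    if (d > 0 && d > original_mapq) out <- d
  }
  as.integer(min(out, cap))
}

#' Classify one read's hits into an assignment category
#'
#' Categories: `antisense` (reverse-strand primary), `unique`
#' (MOD-MAPQ >= 1), and for MOD-MAPQ 0 the rescue categories `same_target`
#' (all hits tied with the primary score point to one reference sequence),
#' `same_codon` (one anticodon across several sequences) or `ambiguous`.
#' The tie set is all hits with AS strictly equal to the primary's AS.
#'
#' @param hits data.frame with columns `target_id`, `strand` (`"+"`/`"-"`),
#'   `score`, `is_primary` (exactly one TRUE).
#' @param mod_mapq Recalibrated MAPQ from [recalibrate_mapq()].
#' @param anticodon_lookup Named character vector mapping every `target_id`
#'   to its isoacceptor label (see [anticodon_lookup()]).
#' @return List with `category`, `anticodon` (NA unless the category
#'   identifies one), `target_id` (NA unless a single target is identified).
#' @export
classify_read <- function(hits, mod_mapq, anticodon_lookup) {
  unknown <- setdiff(hits$target_id, names(anticodon_lookup))
  if (length(unknown))
    stop("target_id '", unknown[1L], "' missing from anticodon lookup")
  p <- hits[hits$is_primary, , drop = FALSE]
  stopifnot(nrow(p) == 1L)
  if (p$strand == "-")
    return(list(category = "antisense", anticodon = NA_character_,
                target_id = NA_character_))
  if (!is.na(mod_mapq) && mod_mapq >= 1L)
    return(list(category = "unique",
                anticodon = unname(anticodon_lookup[p$target_id]),
                target_id = p$target_id))
  top <- hits[!is.na(hits$score) & !is.na(p$score) & hits$score == p$score, ,
              drop = FALSE]
  if (!nrow(top)) top <- p
  targets <- unique(top$target_id)
  if (length(targets) == 1L)
    return(list(category = "same_target",
                anticodon = unname(anticodon_lookup[targets]),
                target_id = targets))
  acs <- unique(unname(anticodon_lookup[targets]))
  if (length(acs) == 1L)
    return(list(category = "same_codon", anticodon = acs,
                target_id = NA_character_))
  list(category = "ambiguous", anticodon = NA_character_,
       target_id = NA_character_)
}

phred_mean <- function(qual) {
  if (is.na(qual) || qual == "*" || !nzchar(qual)) return(NA_real_)
  mean(utf8ToInt(qual) - 33L)
}

# Minimal SAM text reader: returns list(header = character, records = df).
# Field 5 (MAPQ) rewriting needs record-level write access that the BAM
# bindings do not expose, so the recalibration pass works on SAM text and
# keeps every untouched byte identical (including MM/ML tags).
read_sam_lines <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  list(header = lines[is_header], body = lines[!is_header])
}

parse_sam_body <- function(body) {
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("truncated SAM record at body line ", which(nf < 11L)[1L])
  get <- function(k) vapply(parts, `[[`, character(1L), k)
  flag <- as.integer(get(2L))
  as_tag <- rep(NA_integer_, length(body))
  has_as <- grepl("\tAS:i:", body, fixed = TRUE)
  as_tag[has_as] <- as.integer(sub(".*\tAS:i:(-?[0-9]+).*", "\\1",
                                   body[has_as]))
  data.frame(
    qname = get(1L), flag = flag, rname = get(3L),
    pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
    qual = get(11L), score = as_tag,
    unmapped = bitwAnd(flag, 4L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Recalibrate MAPQ across a SAM file and assign reads to anticodons
#'
#' Groups records by read name, computes MOD-MAPQ from the primary and
#' scored secondary hits, classifies every read ([classify_read()]), and
#' optionally writes a SAM identical to the input except that the MAPQ field
#' of primary mapped records carries the recalibrated value (all tags,
#' including MM/ML modification tags, pass through untouched).
#'
#' Supplementary records are excluded from hit sets; secondary records
#' without an AS tag are dropped from recalibration and counted in the
#' `n_dropped_no_score` attribute. Unmapped reads get category `"unmapped"`.
#'
#' @param sam_in Input SAM path (aligned reads with AS tags; secondary
#'   records carry the alternative hits).
#' @param anticodon_lookup Named vector, see [classify_read()].
#' @param sam_out Optional output SAM path.
#' @param cap MOD-MAPQ cap, default 60.
#' @return Assignments data.frame (one row per read): `read_id`, `category`,
#'   `anticodon`, `target_id`, `strand`, `original_mapq`, `mod_mapq`,
#'   `mean_base_quality`, `n_alternatives`.
#' @export
process_alignments <- function(sam_in, anticodon_lookup, sam_out = NULL,
                               cap = 60L) {
  sam <- read_sam_lines(sam_in)
  rec <- parse_sam_body(sam$body)
  use <- !rec$supplementary
  groups <- split(which(use), rec$qname[use])
  n_dropped <- 0L
  new_mapq <- rep(NA_integer_, nrow(rec))

  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    i <- groups[[g]]
    pi <- i[!rec$secondary[i]]
    if (length(pi) != 1L)
      stop("read '", names(groups)[g], "' has ", length(pi),
           " primary records (expected 1)")
    si <- i[rec$secondary[i]]
    if (rec$unmapped[pi]) {
      rows[[g]] <- data.frame(
        read_id = names(groups)[g], category = "unmapped",
        anticodon = NA_character_, target_id = NA_character_,
        strand = NA_character_, original_mapq = NA_integer_,
        mod_mapq = NA_integer_, mean_base_quality = phred_mean(rec$qual[pi]),
        n_alternatives = 0L, stringsAsFactors = FALSE)
      next
    }
    scored <- si[!is.na(rec$score[si])]
    n_dropped <- n_dropped + length(si) - length(scored)
    mq <- recalibrate_mapq(rec$mapq[pi], rec$score[pi],
                           rec$score[scored], cap = cap)
    new_mapq[pi] <- mq
    hit_idx <- c(pi, scored)
    hits <- data.frame(
      target_id = rec$rname[hit_idx],
      strand = ifelse(rec$reverse[hit_idx], "-", "+"),
      score = rec$score[hit_idx],
      is_primary = !rec$secondary[hit_idx],
      stringsAsFactors = FALSE)
    cls <- classify_read(hits, mq, anticodon_lookup)
    rows[[g]] <- data.frame(
      read_id = names(groups)[g], category = cls$category,
      anticodon = cls$anticodon, target_id = cls$target_id,
      strand = ifelse(rec$reverse[pi], "-", "+"),
      original_mapq = rec$mapq[pi], mod_mapq = mq,
      mean_base_quality = phred_mean(rec$qual[pi]),
      n_alternatives = length(scored), stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL

  if (!is.null(sam_out)) {
    body <- sam$body
    change <- which(!is.na(new_mapq) & new_mapq != rec$mapq)
    for (k in change) {
      f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
      f[5L] <- as.character(new_mapq[k])
      body[k] <- paste(f, collapse = "\t")
    }
    writeLines(c(sam$header, body), sam_out)
  }
  if (n_dropped > 0L)
    message(n_dropped, " secondary record(s) without AS tag dropped from ",
            "recalibration")
  attr(assignments, "n_dropped_no_score") <- n_dropped
  assignments
}

#' Convert a SAM file to a sorted, indexed BAM
#' @param sam_path Input SAM.
#' @param bam_prefix Output path without the `.bam` extension (defaults to
#'   the SAM path minus its extension).
#' @return Path to the BAM file.
#' @export
sam_to_bam <- function(sam_path, bam_prefix = sub("\\.sam$", "", sam_path)) {
  Rsamtools::asBam(sam_path, bam_prefix, overwrite = TRUE,
                   indexDestination = TRUE)
}
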