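# Reference curation: collapse a tRNA gene set to unique body sequences,
# attach anticodon/isotype and Sprinzl position maps, and pad with the
# library adapters to form the alignment reference.
#
# Coordinates are 0-based, half-open throughout the package; SAM (1-based)
# and bedMethyl (0-based) are converted at the I/O boundary.

normalize_dna <- function(x) chartr("U", "T", toupper(x))

#' Parse a tRNA gene set
#'
#' Reads gene sequences from a FASTA file and joins the per-gene annotation
#' table (tRNAviz-style; tab-delimited with columns `gene_id`, `isotype`,
#' `anticodon` and, optionally, `sprinzl` holding a comma-separated Sprinzl
#' label per base). Sequences and anticodons are normalised to the DNA
#' alphabet (U -> T), matching the DNA-space reference used for alignment.
#'
#' @param fasta_path Path to the gene FASTA.
#' @param annotation_path Path to the tab-delimited annotation table.
#' @return A data.frame with one row per gene: `gene_id`, `sequence`,
#'   `isotype`, `anticodon`, `sprinzl` (NA when the column is absent).
#' @export
parse_gene_set <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "isotype", "anticodon")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(ids, ann$gene_id)
  if (length(absent))
    stop("no annotation row for FASTA id '", absent[1L], "'")
  idx <- match(ids, ann$gene_id)
  sequence <- normalize_dna(as.character(seqs))
  bad <- grepl("[^ACGT]", sequence) | !nzchar(sequence)
  if (any(bad))
    stop("sequence for '", ids[bad][1L], "' is empty or not over {A,C,G,T,U}")
  anticodon <- normalize_dna(ann$anticodon[idx])
  bad_ac <- nchar(anticodon) != 3L | grepl("[^ACGT]", anticodon)
  if (any(bad_ac))
    stop("malformed anticodon '", ann$anticodon[idx][bad_ac][1L],
         "' for gene '", ids[bad_ac][1L], "'")
  data.frame(
    gene_id   = ids,
    sequence  = sequence,
    isotype   = ann$isotype[idx],
    anticodon = anticodon,
    sprinzl   = if ("sprinzl" %in% names(ann)) ann$sprinzl[idx] else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Collapse a gene set to unique tRNA sequences
#'
#' Genes with byte-identical body sequences are merged into one reference
#' entry (e.g. the 414 hg19 tRNA genes collapse to 267 unique sequences).
#' The representative `seq_id` is the lexicographically smallest member
#' gene id, so references are reproducible across runs.
#'
#' @param genes Gene table from [parse_gene_set()].
#' @return A data.frame of unique sequences: `seq_id`, `sequence`,
#'   `anticodon`, `isotype`, `n_members`, `member_gene_ids` (comma-joined).
#'   The number of distinct isoacceptors (isotype + anticodon) is attached
#'   as attribute `n_anticodons`.
#' @export
deduplicate <- function(genes) {
  grp <- split(seq_len(nrow(genes)), genes$sequence)
  rows <- lapply(grp, function(i) {
    ac <- unique(genes$anticodon[i])
    if (length(ac) > 1L)
      stop("identical sequence with conflicting anticodon annotation: ",
           paste(sort(genes$gene_id[i]), collapse = ", "))
    ord <- order(genes$gene_id[i])
    members <- genes$gene_id[i][ord]
    data.frame(
      seq_id = members[1L],
      sequence = genes$sequence[i[1L]],
      anticodon = ac,
      isotype = genes$isotype[i][ord][1L],
      n_members = length(i),
      member_gene_ids = paste(members, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_anticodons") <-
    length(unique(paste(out$isotype, out$anticodon, sep = "-")))
  out
}

#' Pad unique tRNA sequences with library adapters
#'
#' The sequencing library ligates adapters to the tRNA 3' NCCA overhang;
#' padding the reference with those adapter sequences improves alignment of
#' reads that run into them. Empty adapters are allowed (identity padding).
#'
#' @param uniques Unique-sequence table from [deduplicate()].
#' @param adapter5,adapter3 Adapter sequences (DNA alphabet; may be `""`).
#' @return A data.frame: `seq_id`, `padded_sequence`, `pad5_len`, `pad3_len`,
#'   `body_offset` (0-based start of the tRNA body), `body_length`.
#' @export
build_padded_reference <- function(uniques, adapter5 = "", adapter3 = "") {
  adapter5 <- normalize_dna(adapter5)
  adapter3 <- normalize_dna(adapter3)
  data.frame(
    seq_id = uniques$seq_id,
    padded_sequence = paste0(adapter5, uniques$sequence, adapter3),
    pad5_len = nchar(adapter5),
    pad3_len = nchar(adapter3),
    body_offset = nchar(adapter5),
    body_length = nchar(uniques$sequence),
    stringsAsFactors = FALSE
  )
}

#' Write the padded reference as FASTA
#' @param padded Padded-reference table from [build_padded_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(padded, path) {
  x <- Biostrings::DNAStringSet(padded$padded_sequence)
  names(x) <- padded$seq_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the unique-sequence lookup table
#' @param uniques Table from [deduplicate()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_uniques_table <- function(uniques, path) {
  utils::write.table(uniques, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load Sprinzl position maps for the unique sequences
#'
#' Sprinzl numbering is supplied as input data (a comma-separated label per
#' base in the annotation table, curated upstream); it is never inferred.
#' The map for each unique sequence is taken from its representative gene's
#' annotation row.
#'
#' @param annotation_path The annotation table used by [parse_gene_set()],
#'   which must carry a `sprinzl` column.
#' @param uniques Unique-sequence table from [deduplicate()].
#' @return An object of class `sprinzl_annotation`: a named list mapping
#'   `seq_id` to a character vector of labels (index = 0-based position + 1;
#'   `NA` where a base carries no label).
#' @export
load_sprinzl <- function(annotation_path, uniques) {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!"sprinzl" %in% names(ann))
    stop("annotation table has no 'sprinzl' column")
  maps <- lapply(seq_len(nrow(uniques)), function(i) {
    sid <- uniques$seq_id[i]
    row <- ann[ann$gene_id == sid, , drop = FALSE]
    if (!nrow(row))
      stop("no annotation row for representative gene '", sid, "'")
    labels <- trimws(strsplit(row$sprinzl[1L], ",", fixed = TRUE)[[1L]])
    labels[labels %in% c("", ".", "-")] <- NA_character_
    if (length(labels) != nchar(uniques$sequence[i]))
      stop("Sprinzl label count (", length(labels), ") != body length (",
           nchar(uniques$sequence[i]), ") for '", sid, "'")
    seen <- labels[!is.na(labels)]
    if (anyDuplicated(seen))
      stop("duplicated Sprinzl label '", seen[duplicated(seen)][1L],
           "' on '", sid, "'")
    labels
  })
  names(maps) <- uniques$seq_id
  structure(maps, class = "sprinzl_annotation")
}

#' Sprinzl label at a linear body position
#'
#' @param ann A `sprinzl_annotation` from [load_sprinzl()].
#' @param seq_id Unique-sequence id.
#' @param pos 0-based linear body position(s).
#' @return Character vector: the label, `NA` when the base carries no label,
#'   or the sentinel `"not-in-body"` for positions outside the body (adapter
#'   pads, negative coordinates).
#' @export
sprinzl_of <- function(ann, seq_id, pos) {
  labels <- ann[[seq_id]]
  if (is.null(labels)) stop("unknown seq_id '", seq_id, "'")
  out <- rep("not-in-body", length(pos))
  inside <- !is.na(pos) & pos >= 0L & pos < length(labels)
  out[inside] <- labels[pos[inside] + 1L]
  out[is.na(pos)] <- NA_character_
  out
}

#' Linear body position of a Sprinzl label
#'
#' @inheritParams sprinzl_of
#' @param label Sprinzl label(s), e.g. `"34"`, `"37"`, `"e11"`, `"20a"`.
#' @return Integer vector of 0-based positions; `NA` when the sequence lacks
#'   the label (e.g. no e-arm) -- an absent value, not an error.
#' @export
linear_of <- function(ann, seq_id, label) {
  labels <- ann[[seq_id]]
  if (is.null(labels)) stop("unknown seq_id '", seq_id, "'")
  match(label, labels) - 1L
}

#' Write the Sprinzl map as a long TSV (seq_id, position, label)
#' @param ann A `sprinzl_annotation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sprinzl_table <- function(ann, path) {
  long <- do.call(rbind, lapply(names(ann), function(sid) {
    labels <- ann[[sid]]
    data.frame(seq_id = sid, position = seq_along(labels) - 1L,
               label = labels, stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$label), , drop = FALSE]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Anticodon lookup for unique sequences
#'
#' @param uniques Table from [deduplicate()].
#' @return Named character vector mapping `seq_id` to the isoacceptor label
#'   `"Isotype-ANTICODON"` (e.g. `"Arg-TCT"`), the row naming used in the
#'   expression matrices.
#' @export
anticodon_lookup <- function(uniques) {
  stats::setNames(paste(uniques$isotype, uniques$anticodon, sep = "-"),
                  uniques$seq_id)
}

#' Curate a full alignment reference from a gene set
#'
#' Convenience wrapper running [parse_gene_set()], [deduplicate()],
#' [build_padded_reference()] and [load_sprinzl()] (when the annotation
#' carries labels), optionally writing the reference FASTA and lookup tables.
#'
#' @inheritParams parse_gene_set
#' @inheritParams build_padded_reference
#' @param out_dir Output directory; when non-NULL, `reference.fasta`,
#'   `uniques.tsv` and `sprinzl.tsv` are written there.
#' @return A list: `genes`, `uniques`, `padded`, `sprinzl` (or NULL),
#'   `anticodon_lookup`, and output `paths`.
#' @export
curate_reference <- function(fasta_path, annotation_path,
                             adapter5 = "", adapter3 = "", out_dir = NULL) {
  genes <- parse_gene_set(fasta_path, annotation_path)
  uniques <- deduplicate(genes)
  padded <- build_padded_reference(uniques, adapter5, adapter3)
  sprinzl <- if (any(!is.na(genes$sprinzl)))
    load_sprinzl(annotation_path, uniques) else NULL
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = write_reference_fasta(padded, file.path(out_dir, "reference.fasta")),
      uniques = write_uniques_table(uniques, file.path(out_dir, "uniques.tsv")),
      sprinzl = if (!is.null(sprinzl))
        write_sprinzl_table(sprinzl, file.path(out_dir, "sprinzl.tsv"))
    )
  }
  list(genes = genes, uniques = uniques, padded = padded, sprinzl = sprinzl,
       anticodon_lookup = anticodon_lookup(uniques), paths = paths)
}
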