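# Synthetic-data generator. Emits every input the pipeline consumes -- gene
# FASTA + annotation with planted exact duplicates and 1-nt-apart
# isodecoders, aligned reads (SAM) with alignment scores, co-optimal
# secondary hits, per-position error spikes and antisense contamination, and
# modkit-style bedMethyl pileups -- together with ground-truth tables, so
# every module is testable at desk scale with no downloads. All randomness
# flows from the config seed; a fixed seed gives byte-identical output.

ISOACCEPTOR_POOL <- data.frame(
  isotype = c("Phe", "Gly", "Glu", "Arg", "Lys", "Asp",
              "Leu", "Val", "Ser", "Cys", "Ile", "His"),
  anticodon = c("GAA", "GCC", "TTC", "TCT", "TTT", "GTC",
                "TAA", "AAC", "GCT", "GCA", "GAT", "GTG"),
  stringsAsFactors = FALSE)

default_modified_positions <- function() {
  data.frame(
    anticodon = c("Phe-GAA", "Gly-GCC", "Glu-TTC"),
    label = c("37", "48", "55"),
    error_multiplier = c(4, 2, 2),
    mod_code = c(NA, "m", "17802"),
    true_mod_fraction = c(NA, 0.8, 0.9),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the study conditions for the generator: reference structure
#' (anticodons, isodecoders one substitution apart, exact duplicate gene
#' copies), sequencing depth, planted read categories, the baseline
#' per-position base-calling error (0.08, a realistic figure for nanopore
#' direct RNA over heavily modified tRNA), modification plantings (an
#' error-multiplier for error-rate analysis and/or a true modified fraction
#' for bedMethyl emission, per (isoacceptor, Sprinzl label)), and adapters.
#'
#' @param seed Integer master seed; every emitted file is a deterministic
#'   function of it.
#' @param n_anticodons Number of isoacceptors (drawn from a built-in pool,
#'   Phe-GAA first).
#' @param isodecoders_per_anticodon Body variants per anticodon, each one
#'   substitution from the first.
#' @param duplicate_gene_copies Exact-duplicate gene copies per isodecoder.
#' @param reads_per_sample Reads emitted per sample.
#' @param expression_proportions Anticodon proportions summing to 1, in the
#'   isoacceptor-pool order (Phe-GAA first) or named by isoacceptor label;
#'   default: a mildly uneven deterministic gradient.
#' @param antisense_rate,same_target_rate,same_codon_rate,ambiguous_rate
#'   Planted per-read category probabilities; the remainder is `unique`.
#' @param baseline_error_rate Per-position mismatch+deletion probability at
#'   unmodified positions.
#' @param modified_positions data.frame (`anticodon`, `label`,
#'   `error_multiplier`, `mod_code`, `true_mod_fraction`).
#' @param n_replicates Replicates per condition in multi-sample helpers.
#' @param mod_depth Mean valid-call depth for bedMethyl emission.
#' @param adapter5,adapter3 Adapter sequences used for reference padding
#'   (synthetic defaults, documented as configuration).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_anticodons = 6L,
                              isodecoders_per_anticodon = 2L,
                              duplicate_gene_copies = 2L,
                              reads_per_sample = 2000L,
                              expression_proportions = NULL,
                              antisense_rate = 0.05,
                              same_target_rate = 0.05,
                              same_codon_rate = 0.05,
                              ambiguous_rate = 0.02,
                              baseline_error_rate = 0.08,
                              modified_positions = default_modified_positions(),
                              n_replicates = 2L,
                              mod_depth = 500L,
                              adapter5 = "GGAACTCGGT",
                              adapter3 = "AACCTATCCC") {
  if (n_anticodons > nrow(ISOACCEPTOR_POOL))
    stop("at most ", nrow(ISOACCEPTOR_POOL), " anticodons supported")
  if (is.null(expression_proportions)) {
    w <- seq(2, 1, length.out = n_anticodons)
    expression_proportions <- w / sum(w)
  }
  stopifnot(length(expression_proportions) == n_anticodons,
            abs(sum(expression_proportions) - 1) < 1e-8)
  rates <- c(antisense_rate, same_target_rate, same_codon_rate,
             ambiguous_rate)
  stopifnot(all(rates >= 0), sum(rates) < 1,
            baseline_error_rate >= 0, baseline_error_rate <= 1)
  if (same_codon_rate > 0 && isodecoders_per_anticodon < 2L)
    stop("same_codon_rate > 0 needs at least 2 isodecoders per anticodon")
  if (ambiguous_rate > 0 && n_anticodons < 2L)
    stop("ambiguous_rate > 0 needs at least 2 anticodons")
  structure(list(
    seed = as.integer(seed), n_anticodons = as.integer(n_anticodons),
    isodecoders_per_anticodon = as.integer(isodecoders_per_anticodon),
    duplicate_gene_copies = as.integer(duplicate_gene_copies),
    reads_per_sample = as.integer(reads_per_sample),
    expression_proportions = expression_proportions,
    antisense_rate = antisense_rate, same_target_rate = same_target_rate,
    same_codon_rate = same_codon_rate, ambiguous_rate = ambiguous_rate,
    baseline_error_rate = baseline_error_rate,
    modified_positions = modified_positions,
    n_replicates = as.integer(n_replicates),
    mod_depth = as.integer(mod_depth),
    adapter5 = adapter5, adapter3 = adapter3,
    body_length = 76L), class = "simulation_config")
}

#' Simulate a tRNA gene set with planted duplicate structure
#'
#' Writes a gene FASTA plus annotation table (with per-base Sprinzl labels
#' 1..76) containing, per anticodon, `isodecoders_per_anticodon` bodies one
#' substitution apart, each present as `duplicate_gene_copies` exact-copy
#' genes. Bodies carry the anticodon at Sprinzl 34-36 and end in CCA;
#' positions planted as modification sites are forced to the modification's
#' canonical base.
#'
#' @param config A [simulation_config()].
#' @param out_dir Directory receiving `genes.fasta` and `genes.tsv`.
#' @return List: `fasta`, `annotation` (paths), `genes` (table), and
#'   `truth` (`n_genes`, `n_unique`, `n_anticodons`).
#' @export
simulate_reference <- function(config, out_dir) {
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  L <- config$body_length
  pool <- ISOACCEPTOR_POOL[seq_len(config$n_anticodons), , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (a in seq_len(nrow(pool))) {
    iso <- pool$isotype[a]; ac <- pool$anticodon[a]
    ac_label <- paste(iso, ac, sep = "-")
    body <- sample(bases, L, replace = TRUE)
    body[1L] <- "G"
    body[34:36] <- strsplit(ac, "")[[1L]]
    body[(L - 2L):L] <- c("C", "C", "A")
    mp <- config$modified_positions
    mine <- mp[mp$anticodon == ac_label & !is.na(mp$mod_code), , drop = FALSE]
    if (nrow(mine)) {
      pos1 <- as.integer(mine$label)
      body[pos1] <- MOD_CANONICAL[mine$mod_code]
    }
    for (j in seq_len(config$isodecoders_per_anticodon)) {
      b <- body
      if (j > 1L) {
        dp <- 10L + j   # discriminator position, clear of anticodon and CCA
        b[dp] <- sample(setdiff(bases, body[dp]), 1L)
      }
      for (k in seq_len(config$duplicate_gene_copies)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("tRNA-%s-%d-%d", ac_label, j, k),
          sequence = paste(b, collapse = ""),
          isotype = iso, anticodon = ac,
          sprinzl = paste(seq_len(L), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, rows)
  fasta <- file.path(out_dir, "genes.fasta")
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, fasta)
  annotation <- file.path(out_dir, "genes.tsv")
  utils::write.table(genes[, c("gene_id", "isotype", "anticodon", "sprinzl")],
                     annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, annotation = annotation, genes = genes,
       truth = list(
         n_genes = nrow(genes),
         n_unique = config$n_anticodons * config$isodecoders_per_anticodon,
         n_anticodons = config$n_anticodons))
}

# per-(seq, body position) error rates for one condition; multipliers apply
# in the "experimental" condition (modification present)
planted_error_rates <- function(bundle, config, condition) {
  lut <- bundle$anticodon_lookup
  rates <- lapply(bundle$uniques$seq_id, function(sid) {
    L <- nchar(bundle$uniques$sequence[bundle$uniques$seq_id == sid])
    r <- rep(config$baseline_error_rate, L)
    if (condition == "experimental") {
      mp <- config$modified_positions
      mine <- mp[mp$anticodon == lut[[sid]] & !is.na(mp$error_multiplier), ,
                 drop = FALSE]
      if (nrow(mine)) {
        pos <- linear_of(bundle$sprinzl, sid, mine$label)
        ok <- !is.na(pos)
        r[pos[ok] + 1L] <- pmin(1, config$baseline_error_rate *
                                  mine$error_multiplier[ok])
      }
    }
    r
  })
  names(rates) <- bundle$uniques$seq_id
  rates
}

sam_header <- function(padded) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", padded$seq_id,
            nchar(padded$padded_sequence)),
    paste0("@CO\tsynthetic reads; AS = matches - 2*(mismatches+deletions)"))
}

#' Simulate aligned reads for one sample
#'
#' Emits a SAM file against the curated (padded) reference with per-read
#' planted categories: `unique` reads (either no alternative or one scored
#' strictly lower), MAPQ-0 reads whose co-optimal secondary hit points to
#' the same target, to a sibling isodecoder (same codon) or to a different
#' anticodon (ambiguous), and reverse-strand antisense reads. Per-position
#' mismatch/deletion noise follows the planted error rates (multipliers
#' active when `condition = "experimental"`). Primary records carry MM/ML
#' modification tags so tag passthrough can be verified downstream.
#'
#' @param bundle Curated reference from [curate_reference()] run on
#'   [simulate_reference()] output.
#' @param config A [simulation_config()].
#' @param sample_id Sample name (used in read ids and truth tables).
#' @param condition `"control"` or `"experimental"`.
#' @param out_sam Output SAM path.
#' @param sample_index Integer decorrelating the per-sample random stream
#'   from the shared master seed.
#' @return List: `sam` (path), `reads` (per-read truth: read_id, seq_id,
#'   anticodon, category), `error_rates` (long truth table of planted
#'   per-position rates), `anticodon_counts` (planted counts).
#' @export
simulate_alignments <- function(bundle, config, sample_id,
                                condition = "control", out_sam,
                                sample_index = 1L) {
  set.seed(config$seed + 7919L * as.integer(sample_index))
  uniques <- bundle$uniques
  padded <- bundle$padded
  lut <- bundle$anticodon_lookup
  by_ac <- split(uniques$seq_id, unname(lut[uniques$seq_id]))
  rates <- planted_error_rates(bundle, config, condition)
  body_chars <- lapply(uniques$sequence, function(s) strsplit(s, "")[[1L]])
  names(body_chars) <- uniques$seq_id
  offs <- stats::setNames(padded$body_offset, padded$seq_id)

  n <- config$reads_per_sample
  # anticodon order = first appearance in the uniques table; proportions
  # are defined in that order
  pool_order <- paste(ISOACCEPTOR_POOL$isotype, ISOACCEPTOR_POOL$anticodon,
                      sep = "-")
  ac_order <- pool_order[pool_order %in% unname(lut)]
  props <- config$expression_proportions
  if (!is.null(names(props))) {
    if (!setequal(names(props), ac_order))
      stop("names of expression_proportions must be the simulated ",
           "isoacceptors: ", paste(ac_order, collapse = ", "))
    props <- props[ac_order]
  } else names(props) <- ac_order
  read_ac <- sample(ac_order, n, replace = TRUE, prob = props)
  cat_levels <- c("antisense", "same_target", "same_codon", "ambiguous",
                  "unique")
  cat_probs <- c(config$antisense_rate, config$same_target_rate,
                 config$same_codon_rate, config$ambiguous_rate,
                 1 - config$antisense_rate - config$same_target_rate -
                   config$same_codon_rate - config$ambiguous_rate)
  read_cat <- sample(cat_levels, n, replace = TRUE, prob = cat_probs)
  bases <- c("A", "C", "G", "T")
  qual_char <- "5"  # Phred 20

  lines <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ac <- read_ac[i]
    sids <- by_ac[[ac]]
    sid <- if (length(sids) > 1L) sample(sids, 1L) else sids
    chars <- body_chars[[sid]]
    L <- length(chars)
    p <- rates[[sid]]
    err <- stats::runif(L) < p
    del <- err & (stats::runif(L) < 0.5)
    mism <- err & !del
    seqc <- chars
    for (k in which(mism))
      seqc[k] <- sample(setdiff(bases, chars[k]), 1L)
    keep <- !del
    r <- rle(ifelse(del, "D", "M"))
    cigar <- paste0(r$lengths, r$values, collapse = "")
    n_match <- sum(!err)
    as_p <- n_match - 2L * (sum(mism) + sum(del))
    seq_str <- paste(seqc[keep], collapse = "")
    qual_str <- strrep(qual_char, sum(keep))
    pos1 <- unname(offs[sid]) + 1L
    rid <- sprintf("%s_r%05d", sample_id, i)
    cat_i <- read_cat[i]
    flag <- if (cat_i == "antisense") 16L else 0L
    mapq <- switch(cat_i,
      antisense = 30L,
      same_target = 0L, same_codon = 0L, ambiguous = 0L,
      unique = 0L)  # adjusted below for no-alt unique reads
    alt <- NULL
    if (cat_i == "same_target") {
      alt <- c(sid, as_p)
    } else if (cat_i == "same_codon") {
      sib <- setdiff(sids, sid)
      alt <- c(sample(sib, 1L), as_p)
    } else if (cat_i == "ambiguous") {
      other_ac <- sample(setdiff(ac_order, ac), 1L)
      alt <- c(sample(by_ac[[other_ac]], 1L), as_p)
    } else if (cat_i == "unique") {
      if (stats::runif(1) < 0.5) {
        d <- sample(3:15, 1L)
        alt <- c(sample(setdiff(uniques$seq_id, sid), 1L), as_p - d)
        mapq <- 0L
      } else {
        mapq <- sample(20:60, 1L)
      }
    }
    prim <- paste(rid, flag, sid, pos1, mapq, cigar, "*", 0L, 0L,
                  seq_str, qual_str,
                  paste0("AS:i:", as_p), "MM:Z:C+m?,0;", "ML:B:C,200",
                  sep = "\t")
    if (!is.null(alt)) {
      sec <- paste(rid, 256L, alt[1L], pos1, 0L, cigar, "*", 0L, 0L,
                   "*", "*", paste0("AS:i:", alt[2L]), sep = "\t")
      lines[[i]] <- c(prim, sec)
    } else lines[[i]] <- prim
    truth[[i]] <- data.frame(
      read_id = rid, sample = sample_id, condition = condition,
      seq_id = sid, anticodon = ac, category = cat_i,
      stringsAsFactors = FALSE)
  }
  writeLines(c(sam_header(padded), unlist(lines)), out_sam)
  reads <- do.call(rbind, truth)
  err_truth <- do.call(rbind, lapply(names(rates), function(sid)
    data.frame(seq_id = sid, body_pos = seq_along(rates[[sid]]) - 1L,
               condition = condition, true_error_rate = rates[[sid]],
               stringsAsFactors = FALSE)))
  list(sam = out_sam, reads = reads, error_rates = err_truth,
       anticodon_counts = table(reads$anticodon))
}

#' Simulate modkit-style bedMethyl pileups
#'
#' For every planted modification site (rows of `modified_positions` with a
#' `mod_code`) and every isodecoder of its anticodon, emits one bedMethyl
#' record per sample with `n_valid ~ Poisson(mod_depth)` and
#' `n_mod ~ Binomial(n_valid, true_mod_fraction)`. Unmodified background
#' records (true fraction 0) are emitted at two canonical-base positions
#' per sequence and modification type.
#'
#' @param bundle Curated reference ([curate_reference()]).
#' @param config A [simulation_config()].
#' @param sample_ids Character vector of sample names.
#' @param out_dir Directory receiving `<sample>.bedmethyl`.
#' @return List: `paths` (named by sample) and `truth` (per record:
#'   sample, seq_id, start, mod_code, true_fraction, n_valid, n_mod).
#' @export
simulate_modkit_pileup <- function(bundle, config, sample_ids, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uniques <- bundle$uniques
  lut <- bundle$anticodon_lookup
  offs <- stats::setNames(bundle$padded$body_offset, bundle$padded$seq_id)
  mp <- config$modified_positions
  mp <- mp[!is.na(mp$mod_code), , drop = FALSE]

  site_plan <- list()
  for (r in seq_len(nrow(mp))) {
    for (sid in uniques$seq_id[unname(lut[uniques$seq_id]) == mp$anticodon[r]]) {
      bp <- linear_of(bundle$sprinzl, sid, mp$label[r])
      if (is.na(bp)) next
      site_plan[[length(site_plan) + 1L]] <- data.frame(
        seq_id = sid, start = unname(offs[sid]) + bp,
        mod_code = mp$mod_code[r], true_fraction = mp$true_mod_fraction[r],
        stringsAsFactors = FALSE)
    }
  }
  # unmodified background: first two canonical-base body positions per
  # sequence and mod type that are not already planted
  for (sid in uniques$seq_id) {
    chars <- strsplit(uniques$sequence[uniques$seq_id == sid], "")[[1L]]
    for (code in unique(mp$mod_code)) {
      cand <- which(chars == MOD_CANONICAL[[code]]) - 1L + unname(offs[sid])
      planted <- vapply(site_plan, function(s)
        s$seq_id == sid && s$mod_code == code, logical(1L))
      taken <- if (any(planted))
        unlist(lapply(site_plan[planted], `[[`, "start")) else integer()
      cand <- setdiff(cand, taken)
      for (st in utils::head(cand, 2L))
        site_plan[[length(site_plan) + 1L]] <- data.frame(
          seq_id = sid, start = st, mod_code = code, true_fraction = 0,
          stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, site_plan)

  paths <- character(0)
  truth <- list()
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    set.seed(config$seed + 104729L * si)
    n_valid <- stats::rpois(nrow(plan), config$mod_depth)
    n_mod <- stats::rbinom(nrow(plan), n_valid, plan$true_fraction)
    rec <- data.frame(
      seq_id = plan$seq_id, start = plan$start, strand = "+",
      mod_code = plan$mod_code, n_valid = n_valid, n_mod = n_mod,
      n_canonical = n_valid - n_mod, stringsAsFactors = FALSE)
    path <- file.path(out_dir, paste0(s, ".bedmethyl"))
    write_bedmethyl(rec, path)
    paths[s] <- path
    truth[[s]] <- cbind(sample = s, plan, n_valid = n_valid, n_mod = n_mod,
                        stringsAsFactors = FALSE)
  }
  list(paths = paths, truth = do.call(rbind, truth))
}
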