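# Orchestration: a single run configuration drives reference curation, MAPQ
# recalibration, quantification, error profiling and modification-pileup
# analysis, leaving a manifest of outputs, thresholds and input checksums.

default_thresholds <- function() {
  list(min_read_qual = 4.0, min_mapq = 1L, min_baseq = 2L,
       max_depth = 50000L, min_events = 80L, min_valid_calls = 100L,
       cutoffs = c(0, 10, 20), total = 1000, include_same_target = TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' Missing thresholds are filled with the pipeline defaults (read quality
#' > 4.0, mapping quality >= 1, base quality >= 2, depth cap 50000, >= 80
#' error-profile events, >= 100 valid modification calls, probability
#' cutoffs 0/10/20%, fixed sum 1000).
#'
#' @param path YAML file path.
#' @return Config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- default_thresholds()
  for (k in names(th))
    if (is.null(cfg[[k]])) cfg[[k]] <- th[[k]]
  cfg
}

stage_error <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: reference curation; per-sample MAPQ
#' recalibration and read assignment; anticodon quantification (per-bin QC
#' counts, raw and fixed-sum-normalized expression matrices, mapping QC);
#' optional base-calling-error analysis when `config$error_groups` names
#' experimental and control samples; optional modification-pileup analysis
#' when samples carry bedMethyl paths. A `manifest.json` records package
#' version, thresholds and md5 checksums of all outputs. No stage mutates
#' another stage's inputs.
#'
#' @param config List with elements `out_dir`; `reference` (list: `fasta`,
#'   `annotation`, `adapter5`, `adapter3`); `samples` (data.frame:
#'   `sample_id`, `sam`, optional `condition`, `bedmethyl`, `untreated`
#'   logical); optional `error_groups` (list `experimental`, `control` of
#'   sample ids); optional `orthogonal` (list: `path`,
#'   `min_rate`); plus any thresholds from [default_thresholds()].
#' @return Invisibly, a list with the curated reference bundle, assignment
#'   tables, matrices, error tables, modification sites and the manifest
#'   path.
#' @export
run_pipeline <- function(config) {
  th <- default_thresholds()
  for (k in names(th)) if (is.null(config[[k]])) config[[k]] <- th[[k]]
  out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- config$samples
  if (is.null(samples) || !all(c("sample_id", "sam") %in% names(samples)))
    stop("config error: 'samples' must be a table with sample_id and sam")
  if (!is.null(config$mods) && is.null(samples$bedmethyl))
    stop("config error: modification analysis requested but samples carry ",
         "no bedmethyl paths")

  bundle <- tryCatch(
    curate_reference(config$reference$fasta, config$reference$annotation,
                     config$reference$adapter5 %||% "",
                     config$reference$adapter3 %||% "",
                     out_dir = file.path(out_dir, "reference")),
    error = function(e) stage_error("reference", e))

  assignments <- list(); bins <- list(); sams <- character()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    out_sam <- file.path(out_dir, paste0(s, ".recal.sam"))
    assignments[[s]] <- tryCatch(
      process_alignments(samples$sam[i], bundle$anticodon_lookup,
                         sam_out = out_sam),
      error = function(e) stage_error(paste0("recal:", s), e))
    utils::write.table(assignments[[s]],
                       file.path(out_dir, paste0(s, ".assignments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bins[[s]] <- count_per_mapq_bin(assignments[[s]],
                                    min_read_qual = config$min_read_qual)
    utils::write.table(bins[[s]],
                       file.path(out_dir, paste0(s, ".mapq_bins.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sams[s] <- out_sam
  }

  mat <- tryCatch({
    m <- expression_matrix(bins,
                           include_same_target = config$include_same_target)
    norm <- normalize_fixed_sum(m, total = config$total)
    utils::write.table(data.frame(anticodon = rownames(m), m,
                                  check.names = FALSE),
                       file.path(out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(anticodon = rownames(norm), norm,
                                  check.names = FALSE),
                       file.path(out_dir, "counts_normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(raw = m, normalized = norm)
  }, error = function(e) stage_error("quant", e))
  qc <- do.call(rbind, lapply(names(assignments), function(s)
    cbind(sample = s, mapping_qc(assignments[[s]]))))
  utils::write.table(qc, file.path(out_dir, "mapping_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  errors <- NULL
  if (!is.null(config$error_groups)) {
    errors <- tryCatch({
      ref_fa <- bundle$paths$fasta
      prof <- function(ids) lapply(ids, function(s) {
        bam <- sam_to_bam(sams[[s]])
        error_profile(
          build_pileup(bam, ref_fa, min_mapq = config$min_mapq,
                       min_baseq = config$min_baseq,
                       max_depth = config$max_depth,
                       padded = bundle$padded),
          min_events = config$min_events)
      })
      ep <- prof(config$error_groups$experimental)
      cp <- prof(config$error_groups$control)
      ratio <- condition_log2_ratio(ep, cp)
      utils::write.table(ratio, file.path(out_dir, "error_log2_ratio.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tests <- if (!is.null(bundle$sprinzl))
        global_position_test(ep, cp, bundle$sprinzl) else NULL
      if (!is.null(tests))
        utils::write.table(tests, file.path(out_dir, "position_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(exp_profiles = ep, ctrl_profiles = cp, ratio = ratio,
           tests = tests)
    }, error = function(e) stage_error("errors", e))
  }

  mods <- NULL
  if (!is.null(samples$bedmethyl) && any(nzchar(samples$bedmethyl))) {
    mods <- tryCatch({
      recs <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
        parse_bedmethyl(samples$bedmethyl[i], sample = samples$sample_id[i])))
      ref_seqs <- stats::setNames(bundle$padded$padded_sequence,
                                  bundle$padded$seq_id)
      filt <- filter_mod_records(recs, ref_seqs,
                                 min_valid_calls = config$min_valid_calls)
      untreated <- if (!is.null(samples$untreated))
        samples$sample_id[as.logical(samples$untreated)] else
          samples$sample_id
      sites <- average_sites(filt, samples = untreated)
      if (!is.null(bundle$sprinzl))
        sites <- annotate_sites(sites, bundle$sprinzl, bundle$padded,
                                bundle$uniques)
      utils::write.table(sites, file.path(out_dir, "mod_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (ct in config$cutoffs)
        utils::write.table(threshold_sites(sites, ct),
                           file.path(out_dir,
                                     sprintf("mod_sites_gt%g.tsv", ct)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      comparison <- NULL
      if (!is.null(config$orthogonal) && "label" %in% names(sites)) {
        ortho <- utils::read.delim(config$orthogonal$path,
                                   stringsAsFactors = FALSE)
        roll <- rollup_anticodon(sites)
        roll$trna <- roll$anticodon
        comparison <- compare_orthogonal(
          threshold_sites(roll, config$orthogonal$cutoff %||% 10),
          ortho, min_orthogonal_rate = config$orthogonal$min_rate %||% 0,
          known_trnas = unique(unname(bundle$anticodon_lookup)))
      }
      list(records = recs, filtered = filt, sites = sites,
           comparison = comparison)
    }, error = function(e) stage_error("mods", e))
  }

  inputs <- c(config$reference$fasta, config$reference$annotation,
              samples$sam,
              if (!is.null(samples$bedmethyl)) samples$bedmethyl)
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$|\\.bam(\\.bai)?$", outputs)]
  manifest <- list(
    package = as.character(utils::packageVersion("nanotrna")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    thresholds = config[names(default_thresholds())],
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(bundle = bundle, assignments = assignments, bins = bins,
                 matrices = mat, qc = qc, errors = errors, mods = mods,
                 manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
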