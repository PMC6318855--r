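## End-to-end orchestration: read every input, harmonize, classify
## ambiguity, count evidence, compute metrics, assemble and write reports.

#' Assemble a run configuration
#'
#' @param tools List of `ncl_tool_config` objects (see [tool_config()]).
#' @param gtf,genome Annotation GTF and genome FASTA paths.
#' @param psl_genome,psl_transcripts PSL alignments of the junction
#'   sequences against the genome and the annotated transcripts (produced
#'   externally, e.g. by BLAT on the FASTA from [write_junction_fasta()]).
#' @param sj Splice-junction count table (SJ dialect).
#' @param chimeric Chimeric junction-spanning read records.
#' @param total_raw_reads,total_mapped_reads Library sizes.
#' @param sce_bed Optional SCE BED path.
#' @param quant Optional gene quantification path (RSEM dialect).
#' @return list of class `ncl_run_config`.
#' @export
ncl_run_config <- function(tools, gtf, genome, psl_genome, psl_transcripts,
                           sj, chimeric, total_raw_reads,
                           total_mapped_reads, sce_bed = NULL,
                           quant = NULL) {
  stopifnot(length(tools) >= 1L,
            all(vapply(tools, inherits, logical(1), "ncl_tool_config")))
  names(tools) <- vapply(tools, `[[`, character(1), "tool_name")
  if (anyDuplicated(names(tools))) stop("duplicate tool names")
  structure(list(tools = tools, gtf = gtf, genome = genome,
                 psl_genome = psl_genome,
                 psl_transcripts = psl_transcripts, sj = sj,
                 chimeric = chimeric, total_raw_reads = total_raw_reads,
                 total_mapped_reads = total_mapped_reads,
                 sce_bed = sce_bed, quant = quant),
            class = "ncl_run_config")
}

#' Read a run configuration from YAML (or JSON)
#'
#' Expected layout: top-level keys `gtf`, `genome`, `psl_genome`,
#' `psl_transcripts`, `sj`, `chimeric`, `total_raw_reads`,
#' `total_mapped_reads`, optional `sce_bed`/`quant`, and a `tools` list
#' whose entries carry `tool_name`, `path`, `column_map` (role -> column),
#' and optionally `coordinate_base`, `has_header`, `donor_pos_kind`,
#' `acceptor_pos_kind`, `scope`. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path YAML or JSON file.
#' @return An `ncl_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  tools <- lapply(cfg$tools, function(tc)
    tool_config(tc$tool_name, resolve(tc$path), tc$column_map,
                coordinate_base = tc$coordinate_base %||% 1L,
                has_header = tc$has_header %||% FALSE,
                donor_pos_kind = tc$donor_pos_kind %||% "end",
                acceptor_pos_kind = tc$acceptor_pos_kind %||% "start",
                scope = tc$scope %||% "both"))
  ncl_run_config(tools, resolve(cfg$gtf), resolve(cfg$genome),
                 resolve(cfg$psl_genome), resolve(cfg$psl_transcripts),
                 resolve(cfg$sj), resolve(cfg$chimeric),
                 cfg$total_raw_reads, cfg$total_mapped_reads,
                 sce_bed = resolve(cfg$sce_bed),
                 quant = resolve(cfg$quant))
}

#' Run the full NCL post-screening pipeline
#'
#' Reads every configured input, snaps and merges the per-tool events,
#' classifies alignment ambiguity from the supplied PSL hits, counts the
#' co-linear and out-of-circle evidence, computes the metrics and
#' assembles the result tables; optionally writes the whole report tree.
#'
#' @param config An `ncl_run_config`.
#' @param out_dir Output directory for the TSV report (NULL: in-memory
#'   only).
#' @param mode `"drop_ambiguous"` (ambiguous events to a side table) or
#'   `"keep_all"`.
#' @param snap_dist Junction snap distance (bp).
#' @param flank Junction-flank length per side (nt).
#' @param identity_threshold,score_gap,min_coverage,side_margin Ambiguity
#'   thresholds, see [classify_ambiguity()].
#' @param kappa Score pseudocount.
#' @return Invisibly, a list: events, calls, evidence, ooc, metrics,
#'   results, coverage, cdfs, rejected, seqs.
#' @export
ncl_screen <- function(config, out_dir = NULL,
                       mode = c("drop_ambiguous", "keep_all"),
                       snap_dist = 5L, flank = 100L,
                       identity_threshold = 0.80, score_gap = 3,
                       min_coverage = 0.5, side_margin = 10L,
                       kappa = 0.01) {
  stopifnot(inherits(config, "ncl_run_config"))
  mode <- match.arg(mode)
  annotation <- read_annotation(config$gtf)
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))

  harmonized <- lapply(config$tools, function(tc)
    harmonize_events(read_tool_events(tc), annotation, snap_dist))
  events <- merge_tool_reports(harmonized)
  rejected <- rejection_audit(harmonized)

  seqs <- build_junction_sequences(events, annotation, genome, flank)
  ghits <- read_psl(config$psl_genome)
  if (nrow(ghits)) ghits[, source := "genome"] else ghits[, source := character()]
  thits <- read_psl(config$psl_transcripts)
  if (nrow(thits)) thits[, source := "transcript"]
  else thits[, source := character()]
  hits <- rbind(ghits, thits)
  calls <- classify_events(events, hits, seqs, flank = flank,
                           identity_threshold = identity_threshold,
                           score_gap = score_gap,
                           min_coverage = min_coverage,
                           side_margin = side_margin)

  sj <- read_sj_counts(config$sj)
  chimeric <- read_chimeric(config$chimeric)
  evidence <- count_junction_reads(events, sj, annotation)
  intra_idx <- which(events$locus_class == "intragenic")
  ooc <- .dt_with_key(
    events$key[intra_idx],
    out_of_circle_pairs = vapply(intra_idx, function(i)
      count_out_of_circle_pairs(events[i], chimeric, tol = snap_dist),
      integer(1)))

  aux <- read_auxiliary(config$sce_bed, config$quant)
  tool_scopes <- vapply(config$tools, `[[`, character(1), "scope")
  metrics <- compute_metrics(events, evidence, tool_scopes,
                             config$total_raw_reads,
                             config$total_mapped_reads, kappa = kappa,
                             quant = aux$quant, sce = aux$sce)

  results <- assemble_results(events, calls, evidence, metrics,
                              mode = mode, ooc = ooc)
  coverage <- coverage_summary(events, calls)
  cdfs <- export_distributions(merge(metrics,
                                     calls[, .(key, status)], by = "key"))

  if (!is.null(out_dir)) {
    write_report_tables(results, coverage, cdfs, rejected, out_dir)
    write_junction_fasta(seqs, file.path(out_dir, "junctions.fa"))
    writeLines(c(
      paste0("mode\t", mode), paste0("snap_dist\t", snap_dist),
      paste0("flank\t", flank),
      paste0("identity_threshold\t", identity_threshold),
      paste0("score_gap\t", score_gap),
      paste0("min_coverage\t", min_coverage),
      paste0("side_margin\t", side_margin), paste0("kappa\t", kappa),
      paste0("tools\t", paste(names(config$tools), collapse = ",")),
      paste0("events\t", nrow(events))),
      file.path(out_dir, "run_log.txt"))
  }
  invisible(list(events = events, calls = calls, evidence = evidence,
                 ooc = ooc, metrics = metrics, results = results,
                 coverage = coverage, cdfs = cdfs, rejected = rejected,
                 seqs = seqs, annotation = annotation))
}
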