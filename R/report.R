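## Assemble the intragenic/intergenic union tables, ambiguity side table,
## tool-coverage matrix, supporting-tool histogram and cumulative
## distributions, and write them as deterministic TSVs.

#' Join events, ambiguity calls, evidence and metrics into result tables
#'
#' In `drop_ambiguous` mode rows whose ambiguity status is not `ok` go to a
#' side table, so the accounting identity holds on every run:
#' before-screening total = alt_colinear + multi_hit + after-screening
#' total, per locus class.
#'
#' @param events `ncl_events` table.
#' @param calls data.table from [classify_events()].
#' @param evidence list from [count_junction_reads()]; out-of-circle counts
#'   may be supplied via `ooc`.
#' @param metrics data.table from [compute_metrics()].
#' @param mode `"drop_ambiguous"` (default) or `"keep_all"`.
#' @param ooc Optional data.table(key, out_of_circle_pairs).
#' @return list(intragenic, intergenic, ambiguous, mode); the first two are
#'   the main tables, sorted by chrom, donor_pos, acceptor_pos.
#' @export
assemble_results <- function(events, calls, evidence, metrics,
                             mode = c("drop_ambiguous", "keep_all"),
                             ooc = NULL) {
  mode <- match.arg(mode)
  if (!all(metrics$key %in% events$key))
    stop("internal consistency error: metrics keys absent from events")
  if (!all(calls$key %in% events$key))
    stop("internal consistency error: call keys absent from events")
  full <- merge(as.data.table(events), calls, by = "key", all.x = TRUE)
  full <- merge(full,
                metrics[, setdiff(names(metrics), "locus_class"),
                        with = FALSE], by = "key", all.x = TRUE)
  if (!is.null(ooc)) full <- merge(full, ooc, by = "key", all.x = TRUE)
  else full[, out_of_circle_pairs := NA_integer_]
  full[locus_class != "intragenic", out_of_circle_pairs := NA_integer_]
  setorder(full, donor_chrom, donor_pos, acceptor_pos, acceptor_chrom)
  split_class <- function(cls) full[locus_class == cls]
  intra <- split_class("intragenic")
  inter <- split_class("intergenic")
  if (mode == "drop_ambiguous") {
    ambiguous <- rbind(intra[status != "ok"], inter[status != "ok"])
    intra <- intra[status == "ok"]
    inter <- inter[status == "ok"]
  } else {
    ambiguous <- full[0]
  }
  list(intragenic = intra, intergenic = inter, ambiguous = ambiguous,
       mode = mode)
}

#' Tool-coverage matrix, per-tool summaries and supporting-tool histogram
#'
#' @param events `ncl_events` table.
#' @param calls Optional ambiguity calls; adds per-tool ambiguous counts
#'   and fractions.
#' @return list(matrix = events x tools 0/1 membership, per_tool,
#'   histogram).
#' @export
coverage_summary <- function(events, calls = NULL) {
  if (!nrow(events)) stop("coverage_summary needs at least one event")
  tools <- attr(events, "tools")
  cmat <- count_matrix(events, fill0 = FALSE)
  mem <- !is.na(cmat)
  mm <- .dt_with_key(events$key, locus_class = events$locus_class)
  for (t in tools) mm[, (t) := as.integer(mem[, t])]
  status <- if (!is.null(calls))
    calls$status[match(events$key, calls$key)] else rep(NA_character_,
                                                        nrow(events))
  per_tool <- rbindlist(lapply(tools, function(t) {
    det <- mem[, t]
    data.table(
      tool = t,
      n_detected = sum(det),
      n_specific = sum(det & rowSums(mem) == 1L),
      n_alt_colinear = sum(det & status == "alt_colinear", na.rm = TRUE),
      n_multi_hit = sum(det & status == "multi_hit", na.rm = TRUE),
      frac_ambiguous = if (sum(det))
        sum(det & status != "ok", na.rm = TRUE) / sum(det) else NA_real_)
  }))
  k <- rowSums(mem)
  histogram <- data.table(n_supporting_tools = seq_along(tools))
  histogram[, count := vapply(n_supporting_tools, function(i) sum(k == i),
                              numeric(1))]
  histogram[, fraction := count / nrow(events)]
  list(matrix = mm, per_tool = per_tool, histogram = histogram)
}

#' Empirical cumulative distributions of tau and the NCL score
#'
#' One table per stratum (locus class x ambiguous/non-ambiguous) and
#' metric, as sorted (value, cdf) pairs ready for external KS tests or
#' plotting. Empty strata are omitted with a warning.
#'
#' @param rows data.table with `tau_ncl`, `ncl_score`, `locus_class` and
#'   `status` columns (metrics joined with ambiguity calls).
#' @return Named list of data.table(value, cdf); names are
#'   `<metric>.<locus_class>.<ambiguous|non_ambiguous>`.
#' @export
export_distributions <- function(rows) {
  rows <- as.data.table(rows)
  out <- list()
  for (cls in c("intragenic", "intergenic")) {
    for (amb in c(FALSE, TRUE)) {
      lab <- paste0(cls, ".", if (amb) "ambiguous" else "non_ambiguous")
      sub <- rows[locus_class == cls &
                    (if (amb) status != "ok" else status == "ok")]
      for (metric in c("tau_ncl", "ncl_score")) {
        v <- sort(sub[[metric]][!is.na(sub[[metric]])])
        nm <- paste0(metric, ".", lab)
        if (!length(v)) {
          warning("empty stratum omitted: ", nm)
          next
        }
        out[[nm]] <- data.table(value = v,
                                cdf = seq_along(v) / length(v))
      }
    }
  }
  out
}

.format_tsv <- function(dt) {
  out <- copy(as.data.table(dt))
  for (col in names(out)) {
    x <- out[[col]]
    if (is.double(x))
      out[, (col) := fifelse(is.na(x), NA_character_,
                             sprintf("%.6f", x))]
    else if (is.logical(x))
      out[, (col) := fifelse(is.na(x), NA_character_,
                             fifelse(x, "TRUE", "FALSE"))]
  }
  out
}

#' Write all result tables to a directory as deterministic TSVs
#'
#' Floats are fixed to 6 decimals, missing optional annotations render as
#' "NA" (never 0), and rows keep the fixed (chrom, donor_pos, acceptor_pos)
#' sort, so identical inputs give byte-identical files.
#'
#' @param results list from [assemble_results()].
#' @param coverage list from [coverage_summary()].
#' @param cdfs list from [export_distributions()].
#' @param rejected data.table from [rejection_audit()] (may be NULL).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, coverage, cdfs, rejected,
                                out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(dt, name) {
    p <- file.path(out_dir, name)
    fwrite(.format_tsv(dt), p, sep = "\t", quote = FALSE, na = "NA")
    p
  }
  if (is.null(rejected) || !ncol(rejected))
    rejected <- data.table(tool = character(), donor_chrom = character(),
                           donor_pos = integer(), donor_strand = character(),
                           acceptor_chrom = character(),
                           acceptor_pos = integer(),
                           acceptor_strand = character(), n_ncl = integer(),
                           reason = character())
  paths <- c(
    w(results$intragenic, "intragenic.tsv"),
    w(results$intergenic, "intergenic.tsv"),
    w(results$ambiguous, "ambiguous.tsv"),
    w(rejected, "rejected.tsv"),
    w(coverage$matrix, "coverage_matrix.tsv"),
    w(coverage$per_tool, "per_tool_summary.tsv"),
    w(coverage$histogram, "support_histogram.tsv"))
  for (nm in names(cdfs))
    paths <- c(paths, w(cdfs[[nm]], paste0("cdf_", gsub("\\.", "_", nm),
                                           ".tsv")))
  invisible(paths)
}
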