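## Reliability and expression-context metrics per event: cross-tool
## heterogeneity tau, the NCL score, NCL ratio and circular fraction,
## co-linear junction usage in the host gene, RPM normalization and SCE
## overlap flags.

#' Cross-tool heterogeneity tau of supporting junction read counts
#'
#' For one event, with `N_i` the junction read count reported by tool `i`
#' (zero for tools that did not detect the event) over the `n` compared
#' tools:
#' \deqn{\tau = \sum_i (1 - \log(N_i + 1)/\log(\max(N) + 1)) / (n - 1)}
#' The log base cancels in the ratio. tau ranges from 0 (all tools agree on
#' an identical positive count) to 1 (exactly one tool reports the event);
#' higher values mean greater tool-specificity.
#'
#' @param n_ncl_by_tool Numeric vector over all compared tools, zeros for
#'   non-detectors.
#' @param log_base Base used for both logs (result is invariant to it).
#' @return tau in \[0, 1\]. With a single tool (`n < 2`) the denominator is
#'   degenerate; 0 is returned with a "single-tool comparison" warning.
#' @export
compute_tau <- function(n_ncl_by_tool, log_base = exp(1)) {
  x <- as.numeric(n_ncl_by_tool)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative, no NA")
  if (all(x == 0)) stop("tau undefined: no tool reports the event")
  n <- length(x)
  if (n < 2L) {
    warning("single-tool comparison: tau set to 0")
    return(0)
  }
  mx <- max(x)
  sum(1 - log(x + 1, base = log_base) / log(mx + 1, base = log_base)) /
    (n - 1)
}

#' NCL reliability score
#'
#' \deqn{score = \log_{10}((Median(N)^2 + \kappa) / (\tau + \kappa))}
#' where the median is over the full n-tool vector (zeros included for
#' non-detectors) and `kappa` is a pseudocount avoiding undefined values.
#' A high score means a large median supporting count with little
#' between-tool variation; events seen by a single tool fall near -2.
#'
#' @inheritParams compute_tau
#' @param tau Pre-computed tau for the same vector (defaults to computing
#'   it).
#' @param kappa Pseudocount, default 0.01.
#' @return The score (unbounded, log10 scale).
#' @export
compute_ncl_score <- function(n_ncl_by_tool, tau = NULL, kappa = 0.01) {
  x <- as.numeric(n_ncl_by_tool)
  if (is.null(tau)) tau <- compute_tau(x)
  med <- median(x)
  log10((med^2 + kappa) / (tau + kappa))
}

#' NCL ratio: NCL junction reads against co-linear splicing
#'
#' \deqn{R = 2 N_{NCL} / (2 N_{NCL} + N_D + N_A)}
#' R > 0.5 indicates a higher expression level of the NCL isoform than of
#' its co-linear counterpart at the same boundaries.
#'
#' @param n_ncl NCL junction read count.
#' @param n_d,n_a Unique co-linear junction reads at the donor and acceptor
#'   sites.
#' @return R in \[0, 1\]; `NA` when all three counts are zero. Vectorized.
#' @export
ncl_ratio <- function(n_ncl, n_d, n_a) {
  if (any(c(n_ncl, n_d, n_a) < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  den <- 2 * n_ncl + n_d + n_a
  ifelse(den == 0, NA_real_, 2 * n_ncl / den)
}

#' Circular fraction
#'
#' \deqn{CF = N_{NCL} / (N_{NCL} + N_D + N_A + 1)}
#' The +1 keeps CF defined for all-zero counts; CF > ~1/3 plays the same
#' role as R > 0.5.
#'
#' @inheritParams ncl_ratio
#' @return CF in \[0, 1). Vectorized.
#' @export
circular_fraction <- function(n_ncl, n_d, n_a) {
  if (any(c(n_ncl, n_d, n_a) < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  n_ncl / (n_ncl + n_d + n_a + 1)
}

#' Co-linear junction usage within the host gene
#'
#' `p_d = n_d / sum(donor-gene junction reads)` and symmetrically `p_a`;
#' `p_median` is the median over all annotated junctions of the host gene
#' of (junction count / gene total), the typical junction usage the NCL
#' boundaries are compared against. For intergenic events the two sides
#' have different host genes, so the median is computed per side.
#'
#' @param n_d,n_a Co-linear junction read counts at the event boundaries.
#' @param donor_gene_counts Per-junction unique read counts over all
#'   annotated junctions of the donor-side host gene.
#' @param acceptor_gene_counts Same for the acceptor side (defaults to the
#'   donor gene, the intragenic case).
#' @return list(p_d, p_a, p_median_donor, p_median_acceptor); `NA` where a
#'   gene total is zero.
#' @export
junction_usage <- function(n_d, n_a, donor_gene_counts,
                           acceptor_gene_counts = donor_gene_counts) {
  dtot <- sum(donor_gene_counts)
  atot <- sum(acceptor_gene_counts)
  list(
    p_d = if (length(donor_gene_counts) && dtot > 0) n_d / dtot
          else NA_real_,
    p_a = if (length(acceptor_gene_counts) && atot > 0) n_a / atot
          else NA_real_,
    p_median_donor = if (length(donor_gene_counts) && dtot > 0)
      median(donor_gene_counts / dtot) else NA_real_,
    p_median_acceptor = if (length(acceptor_gene_counts) && atot > 0)
      median(acceptor_gene_counts / atot) else NA_real_)
}

#' Flag junctions falling within SCE intervals
#'
#' @param events `ncl_events` (or any table with the key fields).
#' @param sce_intervals data.table(chrom, start, end), 1-based inclusive,
#'   or `NULL` (no SCE annotation: both flags `NA`).
#' @return data.table(key, sce_donor, sce_acceptor) of logicals.
#' @export
sce_flags <- function(events, sce_intervals = NULL) {
  if (is.null(sce_intervals))
    return(.dt_with_key(events$key, sce_donor = NA, sce_acceptor = NA))
  inside <- function(chrom, pos)
    vapply(seq_along(pos), function(i)
      any(sce_intervals$chrom == chrom[i] &
            sce_intervals$start <= pos[i] &
            sce_intervals$end >= pos[i]), logical(1))
  .dt_with_key(events$key,
               sce_donor = inside(events$donor_chrom, events$donor_pos),
               sce_acceptor = inside(events$acceptor_chrom,
                                     events$acceptor_pos))
}

.first_gene <- function(genes_csv) {
  g <- strsplit(genes_csv, ",", fixed = TRUE)[[1]]
  sort(g)[1L]
}

.host_genes <- function(event) {
  dg <- strsplit(event$donor_genes, ",", fixed = TRUE)[[1]]
  ag <- strsplit(event$acceptor_genes, ",", fixed = TRUE)[[1]]
  shared <- sort(intersect(dg, ag))
  if (length(shared)) list(donor = shared[1L], acceptor = shared[1L])
  else list(donor = sort(dg)[1L], acceptor = sort(ag)[1L])
}

#' Assemble the per-event metrics table
#'
#' Reliability metrics (tau, score, median) use the full per-class tool
#' vector with zeros for non-detectors; abundance metrics (NCL ratio, CF,
#' RPM) use a representative count, the median over the tools that did
#' detect the event.
#'
#' @param events `ncl_events` table.
#' @param evidence list from [count_junction_reads()].
#' @param tool_scopes Named character vector tool -> scope
#'   ("both"/"intragenic"/"intergenic"); determines the compared-tool set
#'   per locus class.
#' @param total_raw_reads,total_mapped_reads Library sizes.
#' @param kappa Pseudocount for the score.
#' @param quant Optional data.table(gene_id, tpm, fpkm) joined per host
#'   gene (donor side); never computed here.
#' @param sce Optional SCE interval table.
#' @return data.table, one metrics row per event.
#' @export
compute_metrics <- function(events, evidence, tool_scopes,
                            total_raw_reads, total_mapped_reads,
                            kappa = 0.01, quant = NULL, sce = NULL) {
  tools <- attr(events, "tools")
  stopifnot(all(tools %in% names(tool_scopes)))
  cm <- count_matrix(events, fill0 = FALSE)
  gc <- evidence$gene_junction_counts
  ev <- merge(.dt_with_key(events$key, idx = seq_len(nrow(events))),
              evidence$events, by = "key", sort = FALSE)
  setorder(ev, idx)
  sf <- sce_flags(events, sce)

  rows <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i]
    in_scope <- tool_scopes[tools] %in% c("both", e$locus_class)
    v <- cm[i, in_scope]
    v0 <- ifelse(is.na(v), 0, v)
    n <- sum(in_scope)
    tau <- if (all(v0 == 0)) NA_real_ else compute_tau(v0)
    score <- if (is.na(tau)) NA_real_
             else compute_ncl_score(v0, tau = tau, kappa = kappa)
    rep_count <- if (all(is.na(v))) NA_real_
                 else median(v[!is.na(v)])
    hosts <- .host_genes(e)
    dgc <- gc[gene_id == hosts$donor, count]
    agc <- gc[gene_id == hosts$acceptor, count]
    ju <- junction_usage(ev$n_d[i], ev$n_a[i], dgc, agc)
    rpm <- compute_rpm(rep_count, total_raw_reads, total_mapped_reads)
    tq <- if (!is.null(quant)) quant[gene_id == hosts$donor] else NULL
    .dt_with_key(
      e$key, locus_class = e$locus_class, n_tools = n,
      median_n_ncl = median(v0), n_ncl = rep_count,
      tau_ncl = tau, ncl_score = score,
      r_ncl = ncl_ratio(rep_count, ev$n_d[i], ev$n_a[i]),
      cf = circular_fraction(rep_count, ev$n_d[i], ev$n_a[i]),
      n_d = ev$n_d[i], n_a = ev$n_a[i],
      p_d = ju$p_d, p_a = ju$p_a,
      p_median_donor = ju$p_median_donor,
      p_median_acceptor = ju$p_median_acceptor,
      rpm_raw = rpm$rpm_raw, rpm_mapped = rpm$rpm_mapped,
      tpm = if (!is.null(tq) && nrow(tq)) tq$tpm[1L] else NA_real_,
      fpkm = if (!is.null(tq) && nrow(tq)) tq$fpkm[1L] else NA_real_,
      sce_donor = sf$sce_donor[i], sce_acceptor = sf$sce_acceptor[i])
  })
  rbindlist(rows)
}
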