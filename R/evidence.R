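## Co-linear junction-read evidence around each NCL junction: unique read
## counts over the annotated introns adjacent to the donor and acceptor
## boundaries, per-gene junction-read totals, and (for intragenic events)
## read pairs whose mate maps entirely outside the putative circle.

## annotated introns deduplicated across transcripts by genomic interval
.dedup_introns <- function(annotation, by_gene = FALSE) {
  cols <- c("chrom", "strand", "intron_start", "intron_end",
            "donor_pos", "acceptor_pos", if (by_gene) "gene_id")
  unique(annotation$introns[, cols, with = FALSE],
         by = c("chrom", "intron_start", "intron_end", if (by_gene) "gene_id"))
}

## join SJ unique counts onto an intron table (match by interval; SJ strand
## may be undetermined, so coordinates decide)
.intron_counts <- function(introns, sj) {
  out <- merge(introns,
               sj[, .(chrom, intron_start, intron_end,
                      count = unique_read_count)],
               by = c("chrom", "intron_start", "intron_end"), all.x = TRUE)
  out[is.na(count), count := 0L]
  out
}

#' Count co-linear junction reads at event boundaries and per host gene
#'
#' For each event, `n_d` is the sum of unique junction reads over all
#' annotated introns whose donor-side exonic boundary equals the event's
#' donor position (the co-linear junctions sharing the donor site, possibly
#' several across isoforms, deduplicated by genomic interval); `n_a` is the
#' symmetric acceptor count. The gene table sums unique reads over every
#' annotated intron of each gene, the denominator of junction usage.
#'
#' @param events `ncl_events` table.
#' @param sj data.table from [read_sj_counts()].
#' @param annotation `ncl_annotation`.
#' @return list(events = data.table(key, n_d, n_a),
#'   gene_totals = data.table(gene_id, gene_junction_total),
#'   gene_junction_counts = per-gene per-intron counts).
#' @export
count_junction_reads <- function(events, sj, annotation) {
  iu <- .dedup_introns(annotation)
  ic <- .intron_counts(iu, sj)
  d_counts <- ic[, .(n = sum(count)), by = .(chrom, strand, donor_pos)]
  a_counts <- ic[, .(n = sum(count)), by = .(chrom, strand, acceptor_pos)]
  ev <- .dt_with_key(events$key)
  dkey <- data.table(chrom = events$donor_chrom,
                     strand = events$donor_strand,
                     donor_pos = events$donor_pos)
  akey <- data.table(chrom = events$acceptor_chrom,
                     strand = events$acceptor_strand,
                     acceptor_pos = events$acceptor_pos)
  dmatch <- d_counts[dkey, on = c("chrom", "strand", "donor_pos")]
  amatch <- a_counts[akey, on = c("chrom", "strand", "acceptor_pos")]
  ev[, n_d := fifelse(is.na(dmatch$n), 0L, as.integer(dmatch$n))]
  ev[, n_a := fifelse(is.na(amatch$n), 0L, as.integer(amatch$n))]

  ig <- .intron_counts(.dedup_introns(annotation, by_gene = TRUE), sj)
  gene_totals <- ig[, .(gene_junction_total = sum(count)), by = gene_id]
  list(events = ev, gene_totals = gene_totals, gene_junction_counts = ig)
}

#' Count read pairs mapping outside an intragenic circle
#'
#' A pair contributes when one read supports the event's NCL junction (its
#' chimeric record matches the event's donor/acceptor sites within `tol`)
#' and the mate's alignment interval lies entirely outside the closed
#' circle interval, or on another chromosome. Mates straddling a circle
#' edge do not count. A positive count argues for an intragenic
#' trans-spliced isoform rather than a circRNA.
#'
#' @param event One-row intragenic event.
#' @param chimeric data.table from [read_chimeric()].
#' @param tol Junction-matching tolerance (bp), mirroring the snap rule.
#' @return Number of distinct qualifying read pairs.
#' @export
count_out_of_circle_pairs <- function(event, chimeric, tol = 5L) {
  if (!identical(event$locus_class, "intragenic"))
    stop("out-of-circle pairs are defined only for intragenic events")
  m <- chimeric[donor_chrom == event$donor_chrom &
                  acceptor_chrom == event$acceptor_chrom &
                  donor_strand == event$donor_strand &
                  acceptor_strand == event$acceptor_strand &
                  abs(donor_pos - event$donor_pos) <= tol &
                  abs(acceptor_pos - event$acceptor_pos) <= tol]
  if (!nrow(m)) return(0L)
  cmin <- min(event$donor_pos, event$acceptor_pos)
  cmax <- max(event$donor_pos, event$acceptor_pos)
  outside <- m$mate_chrom != event$donor_chrom |
    m$mate_end < cmin | m$mate_start > cmax
  length(unique(m$read_id[outside]))
}

#' Junction reads per million raw / uniquely mapped reads
#'
#' @param count Supporting junction read count(s).
#' @param total_raw_reads,total_mapped_reads Library sizes from the
#'   sequencing/alignment logs (not recomputed here).
#' @return list(rpm_raw, rpm_mapped), vectorized over `count`.
#' @export
compute_rpm <- function(count, total_raw_reads, total_mapped_reads) {
  if (is.na(total_raw_reads) || is.na(total_mapped_reads) ||
      total_raw_reads <= 0 || total_mapped_reads <= 0)
    stop("library sizes must be positive")
  list(rpm_raw = count * 1e6 / total_raw_reads,
       rpm_mapped = count * 1e6 / total_mapped_reads)
}
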