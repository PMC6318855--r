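## Snap detector-reported junctions to annotated exon boundaries and merge
## the per-tool reports into one event universe. Only events whose donor AND
## acceptor both lie within the snap distance of an annotated boundary of
## the matching type survive; everything else lands in the audit table.

#' Snap a junction position to the nearest annotated boundary
#'
#' Detector-reported junction coordinates can be off by a few bases due to
#' alignment wobble around the splice site; positions within `max_dist`
#' (default 5 bp) of an annotated boundary are adjusted to it. Ties at equal
#' distance break toward the smaller genomic coordinate. Donor positions
#' must be snapped against the donor-boundary index and acceptor positions
#' against the acceptor index so the two roles can never swap.
#'
#' @param pos 1-based genomic position.
#' @param strand "+" or "-".
#' @param chrom Chromosome name.
#' @param boundary_index data.table with columns chrom, strand, pos (the
#'   `donors` or `acceptors` table of an `ncl_annotation`).
#' @param max_dist Maximum snap distance in bp.
#' @return The snapped position, or `NA_integer_` if no boundary lies within
#'   `max_dist`.
#' @export
snap_junction <- function(pos, strand, chrom, boundary_index, max_dist = 5L) {
  ikey <- data.table(chrom = chrom, strand = strand)
  cand <- boundary_index[ikey, on = c("chrom", "strand"), nomatch = NULL]
  if (!nrow(cand)) return(NA_integer_)
  u <- sort(unique(cand$pos))
  d <- abs(u - pos)
  dmin <- min(d)
  if (dmin > max_dist) return(NA_integer_)
  u[d == dmin][1L]  # u sorted: equal-distance tie -> smaller coordinate
}

.boundary_genes <- function(boundary_index, chrom, strand, pos) {
  ikey <- data.table(chrom = chrom, strand = strand, pos = pos)
  g <- boundary_index[ikey, on = c("chrom", "strand", "pos"),
                      nomatch = NULL]
  sort(unique(g$gene_id))
}

.event_key <- function(dc, dp, ds, ac, ap, as_) {
  sprintf("%s:%d:%s|%s:%d:%s", dc, dp, ds, ac, ap, as_)
}

#' Harmonize raw detector records onto annotated boundaries
#'
#' Each record's donor is snapped against the donor-boundary index and its
#' acceptor against the acceptor-boundary index; records where either side
#' has no annotated boundary within `max_dist` are rejected with a reason
#' (`unannotated_donor`, `unannotated_acceptor`, `unknown_chrom`). Owning
#' gene sets are attached from the exons sharing the snapped boundary, and
#' the event is classed `intragenic` iff the donor and acceptor gene sets
#' intersect.
#'
#' @param records data.table from [read_tool_events()].
#' @param annotation An `ncl_annotation`.
#' @param max_dist Snap distance (bp).
#' @return data.table: the raw coordinates (`raw_donor_pos`,
#'   `raw_acceptor_pos`), snapped `donor_pos`/`acceptor_pos`, `status`
#'   ("ok" or a rejection reason), gene sets (comma-joined), `locus_class`
#'   and the event `key` for accepted rows.
#' @export
harmonize_events <- function(records, annotation, max_dist = 5L) {
  stopifnot(inherits(annotation, "ncl_annotation"))
  n <- nrow(records)
  snapped_d <- rep(NA_integer_, n)
  snapped_a <- rep(NA_integer_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    if (!(records$donor_chrom[i] %in% annotation$chroms) ||
        !(records$acceptor_chrom[i] %in% annotation$chroms)) {
      status[i] <- "unknown_chrom"
      next
    }
    d <- snap_junction(records$donor_pos[i], records$donor_strand[i],
                       records$donor_chrom[i], annotation$donors, max_dist)
    if (is.na(d)) {
      status[i] <- "unannotated_donor"
      next
    }
    a <- snap_junction(records$acceptor_pos[i], records$acceptor_strand[i],
                       records$acceptor_chrom[i], annotation$acceptors,
                       max_dist)
    if (is.na(a)) {
      status[i] <- "unannotated_acceptor"
      next
    }
    snapped_d[i] <- d
    snapped_a[i] <- a
    status[i] <- "ok"
  }
  out <- copy(records)
  out[, `:=`(raw_donor_pos = donor_pos, raw_acceptor_pos = acceptor_pos,
             donor_pos = snapped_d, acceptor_pos = snapped_a,
             status = status)]
  out[, `:=`(donor_genes = NA_character_, acceptor_genes = NA_character_,
             locus_class = NA_character_, key = NA_character_)]
  ok <- which(status == "ok")
  for (i in ok) {
    dg <- .boundary_genes(annotation$donors, out$donor_chrom[i],
                          out$donor_strand[i], out$donor_pos[i])
    ag <- .boundary_genes(annotation$acceptors, out$acceptor_chrom[i],
                          out$acceptor_strand[i], out$acceptor_pos[i])
    set(out, i, "donor_genes", paste(dg, collapse = ","))
    set(out, i, "acceptor_genes", paste(ag, collapse = ","))
    set(out, i, "locus_class",
        if (length(intersect(dg, ag))) "intragenic" else "intergenic")
    set(out, i, "key",
        .event_key(out$donor_chrom[i], out$donor_pos[i], out$donor_strand[i],
                   out$acceptor_chrom[i], out$acceptor_pos[i],
                   out$acceptor_strand[i]))
  }
  out[]
}

.event_cols <- c("key", "donor_chrom", "donor_pos", "donor_strand",
                 "acceptor_chrom", "acceptor_pos", "acceptor_strand",
                 "donor_genes", "acceptor_genes", "locus_class")

#' Merge harmonized per-tool reports into one event universe
#'
#' Events are grouped by the snapped junction key; the union of all tools'
#' events is kept with one per-tool count column each (`NA` = the tool did
#' not detect the event). If one tool reports the same key more than once
#' the counts are summed with a warning.
#'
#' @param harmonized Named list (tool name -> data.table from
#'   [harmonize_events()]); only `status == "ok"` rows are used.
#' @return An `ncl_events` data.table: key fields, gene sets, locus class,
#'   `n_supporting_tools` and one `n_ncl.<tool>` column per tool (in input
#'   order, kept in the `tools` attribute).
#' @export
merge_tool_reports <- function(harmonized) {
  stopifnot(length(harmonized) >= 1L, !is.null(names(harmonized)))
  tools <- names(harmonized)
  long <- rbindlist(lapply(tools, function(t) {
    h <- harmonized[[t]]
    h <- h[status == "ok"]
    if (!nrow(h)) return(NULL)
    h2 <- h[, .(n_ncl = sum(n_ncl), dup = .N > 1L), by = .event_cols]
    if (any(h2$dup))
      warning("tool '", t, "': ", sum(h2$dup),
              " event key(s) reported more than once; counts summed")
    h2[, dup := NULL][, tool := t]
  }))
  count_cols <- paste0("n_ncl.", tools)
  if (is.null(long) || !nrow(long)) {
    warning("no harmonized events from any tool")
    empty <- setnames(
      as.data.table(c(
        list(key = character(), donor_chrom = character(),
             donor_pos = integer(), donor_strand = character(),
             acceptor_chrom = character(), acceptor_pos = integer(),
             acceptor_strand = character(), donor_genes = character(),
             acceptor_genes = character(), locus_class = character(),
             n_supporting_tools = integer()),
        setNames(rep(list(integer()), length(tools)), count_cols))),
      c(.event_cols, "n_supporting_tools", count_cols))
    setattr(empty, "tools", tools)
    setattr(empty, "class", c("ncl_events", class(empty)))
    return(empty)
  }
  wide <- dcast(long, as.formula(paste(paste(.event_cols, collapse = " + "),
                                       "~ tool")), value.var = "n_ncl")
  present <- setdiff(names(wide), .event_cols)
  setnames(wide, present, paste0("n_ncl.", present))
  for (cc in setdiff(count_cols, names(wide))) wide[, (cc) := NA_integer_]
  setcolorder(wide, c(.event_cols, count_cols))
  wide[, n_supporting_tools :=
         rowSums(!is.na(as.matrix(.SD))), .SDcols = count_cols]
  setcolorder(wide, c(.event_cols, "n_supporting_tools", count_cols))
  setorder(wide, donor_chrom, donor_pos, acceptor_pos)
  setattr(wide, "tools", tools)
  setattr(wide, "class", c("ncl_events", class(wide)))
  wide
}

#' Per-tool junction read-count matrix of an event set
#' @param events An `ncl_events` table.
#' @param fill0 Replace NA (tool did not detect) with 0.
#' @return Numeric matrix, events x tools.
#' @export
count_matrix <- function(events, fill0 = TRUE) {
  tools <- attr(events, "tools")
  m <- as.matrix(events[, paste0("n_ncl.", tools), with = FALSE])
  colnames(m) <- tools
  rownames(m) <- events$key
  if (fill0) m[is.na(m)] <- 0
  m
}

#' Rejection audit table across tools
#' @param harmonized Named list as in [merge_tool_reports()].
#' @return data.table (tool, raw coordinates, reason) of rejected records.
#' @export
rejection_audit <- function(harmonized) {
  rbindlist(lapply(names(harmonized), function(t) {
    h <- harmonized[[t]][status != "ok"]
    if (!nrow(h)) return(NULL)
    data.table(tool = t, donor_chrom = h$donor_chrom,
               donor_pos = h$raw_donor_pos, donor_strand = h$donor_strand,
               acceptor_chrom = h$acceptor_chrom,
               acceptor_pos = h$raw_acceptor_pos,
               acceptor_strand = h$acceptor_strand, n_ncl = h$n_ncl,
               reason = h$status)
  }))
}
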