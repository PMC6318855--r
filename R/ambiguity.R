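## Build the (up to) 200 bp junction-flanking concatenated sequence for each
## event and classify alignment ambiguity from its hits: an alternative
## co-linear explanation (a single high-identity alignment reading straight
## through the junction) or multiple genomic loci with near-equal scores.

.tx_exons <- function(annotation, tx) {
  te <- annotation$tx_exons[[tx]]
  if (!is.null(te)) return(te)
  annotation$exons[transcript_id == tx][order(exon_rank)]
}

## spliced sequence of a set of exons of one transcript, transcript
## orientation; exdt in any order
.spliced_seq <- function(exdt, genome) {
  exdt <- exdt[order(start)]
  chrom <- exdt$chrom[1L]
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from genome")
  segs <- vapply(seq_len(nrow(exdt)), function(i)
    as.character(Biostrings::subseq(genome[[chrom]], exdt$start[i],
                                    exdt$end[i])), character(1))
  s <- paste(segs, collapse = "")
  if (exdt$strand[1L] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

## transcripts owning a boundary, with the exon rank of the owning exon
.owning_tx <- function(boundary_index, chrom, strand, pos) {
  ikey <- data.table(chrom = chrom, strand = strand, pos = pos)
  boundary_index[ikey, on = c("chrom", "strand", "pos"), nomatch = NULL]
}

#' Build the junction-flanking concatenated sequence for one event
#'
#' The donor flank is the last `flank` nt of spliced transcript sequence
#' ending at the donor boundary (walking upstream across exon junctions of
#' an owning transcript) and the acceptor flank the first `flank` nt
#' starting at the acceptor boundary; the two are concatenated with the
#' junction at offset `donor_flank_len`. Flanks follow the spliced
#' transcript, not the genome, because the flanking sequence of an NCL
#' junction is exonic. When several transcripts own a boundary the one
#' yielding the longest flank wins, ties broken by transcript id. For an
#' intragenic event whose exonic circle (acceptor..donor span within one
#' transcript) is shorter than `2 * flank`, the full circle sequence is
#' used once, split evenly between the two flanks. Minus-strand sequence is
#' reverse-complemented.
#'
#' @param event List or one-row data.table with the harmonized key fields.
#' @param annotation `ncl_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param flank Maximum flank length per side (nt).
#' @return list(key, sequence, donor_flank_len, acceptor_flank_len); the
#'   junction midpoint offset equals `donor_flank_len`.
#' @export
build_junction_sequence <- function(event, annotation, genome, flank = 100L) {
  dtx <- .owning_tx(annotation$donors, event$donor_chrom,
                    event$donor_strand, event$donor_pos)
  atx <- .owning_tx(annotation$acceptors, event$acceptor_chrom,
                    event$acceptor_strand, event$acceptor_pos)
  if (!nrow(dtx) || !nrow(atx))
    stop("junction not on any annotated transcript: ", event$key %||% "")
  key <- event$key %||% .event_key(event$donor_chrom, event$donor_pos,
                                   event$donor_strand, event$acceptor_chrom,
                                   event$acceptor_pos, event$acceptor_strand)

  ## circle path: a transcript owning both boundaries with the acceptor not
  ## after the donor in transcript direction
  shared <- merge(dtx[, .(transcript_id, jd = exon_rank)],
                  atx[, .(transcript_id, ja = exon_rank)],
                  by = "transcript_id")
  shared <- shared[ja <= jd]
  if (nrow(shared)) {
    circ_len <- vapply(seq_len(nrow(shared)), function(i) {
      ex <- .tx_exons(annotation, shared$transcript_id[i])
      sum(ex[exon_rank >= shared$ja[i] & exon_rank <= shared$jd[i],
             end - start + 1L])
    }, integer(1))
    pick <- order(-circ_len, shared$transcript_id)[1L]
    L <- circ_len[pick]
    if (L < 2L * flank) {
      ex <- .tx_exons(annotation, shared$transcript_id[pick])
      circ <- .spliced_seq(ex[exon_rank >= shared$ja[pick] &
                                exon_rank <= shared$jd[pick]], genome)
      d <- as.integer(ceiling(L / 2))
      a <- L - d
      seqc <- paste0(substr(circ, L - d + 1L, L), substr(circ, 1L, a))
      return(list(key = key, sequence = seqc, donor_flank_len = d,
                  acceptor_flank_len = a))
    }
  }

  ## independent flanks
  donor_side <- function() {
    avail <- vapply(seq_len(nrow(dtx)), function(i) {
      ex <- .tx_exons(annotation, dtx$transcript_id[i])
      sum(ex[exon_rank <= dtx$exon_rank[i], end - start + 1L])
    }, integer(1))
    eff <- pmin(avail, flank)
    pick <- order(-eff, dtx$transcript_id)[1L]
    ex <- .tx_exons(annotation, dtx$transcript_id[pick])
    s <- .spliced_seq(ex[exon_rank <= dtx$exon_rank[pick]], genome)
    substr(s, nchar(s) - eff[pick] + 1L, nchar(s))
  }
  acceptor_side <- function() {
    avail <- vapply(seq_len(nrow(atx)), function(i) {
      ex <- .tx_exons(annotation, atx$transcript_id[i])
      sum(ex[exon_rank >= atx$exon_rank[i], end - start + 1L])
    }, integer(1))
    eff <- pmin(avail, flank)
    pick <- order(-eff, atx$transcript_id)[1L]
    ex <- .tx_exons(annotation, atx$transcript_id[pick])
    s <- .spliced_seq(ex[exon_rank >= atx$exon_rank[pick]], genome)
    substr(s, 1L, eff[pick])
  }
  df <- donor_side()
  af <- acceptor_side()
  list(key = key, sequence = paste0(df, af),
       donor_flank_len = nchar(df), acceptor_flank_len = nchar(af))
}

#' Build junction sequences for an event table
#' @inheritParams build_junction_sequence
#' @param events `ncl_events` table.
#' @return data.table(key, sequence, donor_flank_len, acceptor_flank_len).
#' @export
build_junction_sequences <- function(events, annotation, genome,
                                     flank = 100L) {
  rbindlist(lapply(seq_len(nrow(events)), function(i)
    build_junction_sequence(events[i], annotation, genome, flank)))
}

#' Write junction sequences as FASTA for external alignment
#' @param seqs data.table from [build_junction_sequences()].
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$key))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Score an alignment hit (web-BLAT convention)
#'
#' score = matches + repMatches - misMatches - qNumInsert - tNumInsert;
#' identity = (matches + repMatches) / qSize, i.e. identity over the whole
#' query, so partial-coverage hits score a proportionally lower identity.
#'
#' @param hits One or more PSL rows.
#' @return data.table(score, identity), one row per hit.
#' @export
score_hit <- function(hits) {
  hits <- as.data.table(hits)
  if (any(hits$qSize == 0)) stop("hit with qSize = 0")
  data.table(
    score = hits$matches + hits$repMatches - hits$misMatches -
      hits$qNumInsert - hits$tNumInsert,
    identity = (hits$matches + hits$repMatches) / hits$qSize)
}

#' Find an alternative co-linear explanation among alignment hits
#'
#' A hit explains the junction co-linearly iff a single alignment covers the
#' junction midpoint with at least `side_margin` query bases on each side
#' and its query-wide identity exceeds `identity_threshold`. Such a hit
#' means the junction reads through in normal exon order (for example via
#' another isoform of the host gene) and the NCL call is suspect.
#'
#' @param hits PSL rows for this query (genome and/or transcript targets).
#' @param junction_seq list from [build_junction_sequence()]; supplies the
#'   midpoint offset.
#' @param identity_threshold Query-wide identity above which a
#'   midpoint-crossing hit counts (strict inequality).
#' @param side_margin Minimum query bases required on each side of the
#'   midpoint, guarding against trivially clipped hits.
#' @return The best qualifying hit (one-row data.table with score/identity
#'   appended), or `NULL`.
#' @export
find_alt_colinear <- function(hits, junction_seq, identity_threshold = 0.80,
                              side_margin = 10L) {
  hits <- as.data.table(hits)
  if (!nrow(hits)) return(NULL)
  mid <- junction_seq$donor_flank_len
  sc <- score_hit(hits)
  ok <- hits$qStart <= (mid - side_margin) &
    hits$qEnd >= (mid + side_margin) &
    sc$identity > identity_threshold
  if (!any(ok)) return(NULL)
  h <- cbind(hits[ok], sc[ok])
  h[order(-identity, -score)][1L]
}

#' Flag queries hitting multiple genomic loci with near-equal scores
#'
#' Among hits covering at least `min_coverage` of the query, distinct target
#' loci are compared; the flag fires iff two or more loci score within
#' `(best - score_gap, best]`. Hits at the event's own donor/acceptor locus
#' pair (the expected split alignment of a genuine NCL junction) are
#' collapsed into a single locus, as are duplicate hits at an identical
#' target interval.
#'
#' @param hits PSL rows against the genome.
#' @param score_gap Score window below the best locus (strict).
#' @param min_coverage Minimum query fraction a hit must cover to define a
#'   locus.
#' @param self_intervals Optional data.table(chrom, start, end), 1-based
#'   inclusive: target regions belonging to the event's own junction.
#' @return Logical flag with attributes `best_score` and `runner_up`
#'   (second-best locus score, `NA` if fewer than two loci).
#' @export
find_multi_hit <- function(hits, score_gap = 3, min_coverage = 0.5,
                           self_intervals = NULL) {
  hits <- as.data.table(hits)
  res <- function(flag, best, runner)
    structure(flag, best_score = best, runner_up = runner)
  if (!nrow(hits)) return(res(FALSE, NA_real_, NA_real_))
  sc <- score_hit(hits)
  cov <- (hits$qEnd - hits$qStart) / hits$qSize
  keep <- cov >= min_coverage
  if (!any(keep)) return(res(FALSE, NA_real_, NA_real_))
  h <- data.table(tName = hits$tName[keep], tStart = hits$tStart[keep],
                  tEnd = hits$tEnd[keep], score = sc$score[keep])
  h[, locus := paste(tName, tStart, tEnd, sep = ":")]
  if (!is.null(self_intervals) && nrow(self_intervals)) {
    is_self <- vapply(seq_len(nrow(h)), function(i)
      any(self_intervals$chrom == h$tName[i] &
            h$tStart[i] + 1L <= self_intervals$end &
            h$tEnd[i] >= self_intervals$start), logical(1))
    h[is_self, locus := ".self"]
  }
  loci <- h[, .(score = max(score)), by = locus]
  srt <- sort(loci$score, decreasing = TRUE)
  best <- srt[1L]
  runner <- if (length(srt) >= 2L) srt[2L] else NA_real_
  res(sum(loci$score > best - score_gap) >= 2L, best, runner)
}

#' Classify one event's alignment ambiguity
#'
#' Precedence: `alt_colinear` over `multi_hit` (an event can satisfy both;
#' it is reported once, with both raw flags retained in the evidence
#' columns). Multi-hit loci are assessed on genome-target hits only;
#' alternative co-linear explanations may come from genome or transcript
#' targets. A query with no hits at all is reported `ok` with zero scores
#' and a warning.
#'
#' @param event One-row event (needs `key`).
#' @param hits PSL rows for this query; an optional `source` column
#'   ("genome"/"transcript") restricts the multi-hit check.
#' @param junction_seq list from [build_junction_sequence()].
#' @inheritParams find_alt_colinear
#' @inheritParams find_multi_hit
#' @return One-row data.table: key, status (ok/alt_colinear/multi_hit),
#'   best_hit_score, runner_up_score, colinear_identity, alt_colinear,
#'   multi_hit.
#' @export
classify_ambiguity <- function(event, hits, junction_seq,
                               identity_threshold = 0.80, score_gap = 3,
                               min_coverage = 0.5, side_margin = 10L,
                               self_intervals = NULL) {
  hits <- as.data.table(hits)
  if (!nrow(hits)) {
    warning("junction sequence aligned nowhere: ", event$key)
    return(.dt_with_key(event$key, status = "ok", best_hit_score = 0,
                        runner_up_score = NA_real_,
                        colinear_identity = NA_real_, alt_colinear = FALSE,
                        multi_hit = FALSE))
  }
  ghits <- if ("source" %in% names(hits)) hits[source == "genome"] else hits
  alt <- find_alt_colinear(hits, junction_seq, identity_threshold,
                           side_margin)
  mh <- find_multi_hit(ghits, score_gap, min_coverage, self_intervals)
  sc <- score_hit(hits)
  .dt_with_key(
    event$key,
    status = if (!is.null(alt)) "alt_colinear"
             else if (isTRUE(as.logical(mh))) "multi_hit" else "ok",
    best_hit_score = max(sc$score),
    runner_up_score = attr(mh, "runner_up"),
    colinear_identity = if (!is.null(alt)) alt$identity else NA_real_,
    alt_colinear = !is.null(alt),
    multi_hit = as.logical(mh))
}

#' Classify ambiguity for a whole event table
#'
#' @param events `ncl_events` table.
#' @param hits PSL rows with a `qName` column (event keys) and a `source`
#'   column tagging genome vs transcript targets.
#' @param seqs data.table from [build_junction_sequences()].
#' @param flank Flank length used to build `seqs`; also defines the
#'   self-locus window (boundary +/- flank) on each side.
#' @inheritParams classify_ambiguity
#' @return data.table, one classification row per event.
#' @export
classify_events <- function(events, hits, seqs, flank = 100L,
                            identity_threshold = 0.80, score_gap = 3,
                            min_coverage = 0.5, side_margin = 10L) {
  hits <- as.data.table(hits)
  rbindlist(lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i]
    js <- as.list(seqs[key == ev$key][1L])
    self_iv <- data.table(
      chrom = c(ev$donor_chrom, ev$acceptor_chrom),
      start = pmax(1L, c(ev$donor_pos, ev$acceptor_pos) - flank),
      end = c(ev$donor_pos, ev$acceptor_pos) + flank)
    classify_ambiguity(ev, hits[qName == ev$key], js, identity_threshold,
                       score_gap, min_coverage, side_margin, self_iv)
  }))
}
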