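## Self-contained fixture generator: a random genome with multi-exon genes,
## planted NCL events of every class (circular, intragenic trans-spliced,
## fusion), per-tool detection tables with controlled dispersion and
## coordinate jitter, directly-authored PSL/SJ/chimeric evidence files, and
## a ground-truth manifest. Everything is seeded and byte-deterministic, so
## the whole pipeline is testable without downloads or external aligners.

#' Simulation configuration
#'
#' Defaults describe the package's reference desk-scale study: a six-tool
#' panel (each tool reporting both locus classes), 30 circRNA + 10
#' intragenic trans-spliced + 10 fusion events of which 10 carry planted
#' alternative co-linear evidence and 10 planted multi-locus evidence,
#' detection probability 0.8 and log-normal count dispersion 0.25.
#'
#' @param seed Integer seed; each generator stage derives its own stream
#'   from it (seed + a small fixed offset).
#' @param n_genes Number of non-overlapping multi-exon genes.
#' @param exons_per_gene,exon_len,intron_len,intergenic_gap Ranges
#'   (min, max) for gene structure, in bp.
#' @param n_chroms Number of chromosomes (genes distributed round-robin).
#' @param n_circ,n_trans,n_fusion Planted event counts per class.
#' @param n_alt_colinear,n_multihit How many planted events receive
#'   ambiguous-alignment evidence of each kind.
#' @param tools Tool panel names.
#' @param detection_prob Per-tool probability of detecting an event.
#' @param dispersion sdlog of the multiplicative log-normal noise on
#'   reported counts (0 = noiseless).
#' @param jitter_frac,jitter_max Fraction of emitted records whose
#'   coordinates are jittered, and the maximum absolute jitter (bp).
#' @param total_raw_reads,total_mapped_reads Library sizes recorded in the
#'   run config.
#' @param n_sce Number of donor boundaries covered by a planted SCE
#'   interval.
#' @param isoform_frac Fraction of genes given a second, exon-skipping
#'   isoform.
#' @param flank Junction flank length the alignment fixtures assume.
#' @param chrom_len Optional fixed chromosome length; error if the genes do
#'   not fit (NULL: sized automatically).
#' @return list of class `ncl_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 36L, exons_per_gene = c(4L, 8L),
                       exon_len = c(100L, 300L), intron_len = c(100L, 400L),
                       intergenic_gap = c(800L, 1500L), n_chroms = 2L,
                       n_circ = 30L, n_trans = 10L, n_fusion = 10L,
                       n_alt_colinear = 10L, n_multihit = 10L,
                       tools = paste0("tool", LETTERS[1:6]),
                       detection_prob = 0.8, dispersion = 0.25,
                       jitter_frac = 0.3, jitter_max = 3L,
                       total_raw_reads = 2e7, total_mapped_reads = 1.6e7,
                       n_sce = 5L, isoform_frac = 0.3, flank = 100L,
                       chrom_len = NULL) {
  stopifnot(n_circ >= 0, n_trans >= 0, n_fusion >= 0,
            n_alt_colinear >= 0, n_multihit >= 0,
            detection_prob >= 0, detection_prob <= 1,
            jitter_frac >= 0, jitter_frac <= 1, jitter_max <= 5L,
            exons_per_gene[1] >= 4L)
  if (n_alt_colinear + n_multihit > n_circ + n_trans + n_fusion)
    stop("more planted ambiguous events than events")
  structure(as.list(environment()), class = "ncl_sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.TAIL_PAD <- 6000L  # gene-free tail per chromosome; hosts decoy loci

#' Simulate a reference genome and annotation
#'
#' Genes are placed without overlap on alternating strands across the
#' chromosomes. When multi-hit fixtures are requested, a 200 bp exonic
#' segment of the first gene is copied into the gene-free tail of the last
#' chromosome (twice), so decoy loci carry genuinely aliasing sequence;
#' when alternative co-linear fixtures are requested, a fraction of genes
#' get a second exon-skipping isoform, the structure that lets an NCL
#' junction of one isoform read through co-linearly on another.
#'
#' @param config An `ncl_sim_config`.
#' @return list(genome = named `DNAStringSet`, exons = data.table with one
#'   row per transcript exon, gene_structures).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "ncl_sim_config"))
  set.seed(config$seed)
  rint <- function(rng) sample(rng[1]:rng[2], 1L)
  chroms <- sprintf("chrS%d", seq_len(config$n_chroms))
  cursor <- setNames(rep(1000L, config$n_chroms), chroms)
  exon_rows <- vector("list", config$n_genes)
  iso_genes <- character()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    chrom <- chroms[(g - 1L) %% config$n_chroms + 1L]
    strand <- if (g %% 2L) "+" else "-"
    k <- rint(config$exons_per_gene)
    elens <- vapply(seq_len(k), function(i) rint(config$exon_len),
                    integer(1))
    ilens <- vapply(seq_len(k - 1L), function(i) rint(config$intron_len),
                    integer(1))
    starts <- integer(k)
    pos <- cursor[chrom]
    for (i in seq_len(k)) {
      starts[i] <- pos
      pos <- pos + elens[i] + if (i < k) ilens[i] else 0L
    }
    cursor[chrom] <- pos + rint(config$intergenic_gap)
    ends <- starts + elens - 1L
    rows <- list(data.table(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                            chrom = chrom, strand = strand,
                            start = starts, end = ends))
    if (runif(1) < config$isoform_frac ||
        (config$n_alt_colinear > 0L && g == 1L)) {
      skip <- sample(2:(k - 1L), 1L)
      rows <- c(rows, list(
        data.table(gene_id = gid, transcript_id = paste0(gid, ".t2"),
                   chrom = chrom, strand = strand,
                   start = starts[-skip], end = ends[-skip])))
      iso_genes <- c(iso_genes, gid)
    }
    exon_rows[[g]] <- rbindlist(rows)
  }
  exons <- rbindlist(exon_rows)
  lens <- vapply(chroms, function(ch) {
    mx <- exons[chrom == ch, if (.N) max(end) else 0L]
    as.integer(max(mx, 0L) + .TAIL_PAD)
  }, integer(1))
  if (!is.null(config$chrom_len) && any(lens > config$chrom_len))
    stop("genes do not fit in the requested chromosome length")
  genome_chr <- lapply(lens, .rand_dna)
  ## plant aliasing copies of an exonic segment in the last chrom's tail
  if (config$n_multihit > 0L) {
    seg_src <- exons[gene_id == "G001" & transcript_id == "G001.t1"][1L]
    seg_len <- min(200L, seg_src$end - seg_src$start + 1L)
    seg <- substr(genome_chr[[seg_src$chrom]], seg_src$start,
                  seg_src$start + seg_len - 1L)
    last <- length(chroms)
    for (off in c(5000L, 3000L)) {
      at <- lens[last] - off + 1L
      substr(genome_chr[[last]], at, at + seg_len - 1L) <- seg
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(genome_chr))
  names(genome) <- chroms
  list(genome = genome, exons = exons, iso_genes = iso_genes)
}

.write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

.write_gtf <- function(exons, path) {
  setorder(exons, gene_id, transcript_id, start)
  attr_str <- function(gid, tid = NULL)
    paste0("gene_id \"", gid, "\"; ",
           if (!is.null(tid)) paste0("transcript_id \"", tid, "\"; "),
           "gene_name \"", gid, "\";")
  lines <- character()
  for (gid in unique(exons$gene_id)) {
    ge <- exons[gene_id == gid]
    lines <- c(lines, paste(ge$chrom[1], "sim", "gene", min(ge$start),
                            max(ge$end), ".", ge$strand[1], ".",
                            attr_str(gid), sep = "\t"))
    for (tid in unique(ge$transcript_id)) {
      te <- ge[transcript_id == tid]
      lines <- c(lines,
                 paste(te$chrom[1], "sim", "transcript", min(te$start),
                       max(te$end), ".", te$strand[1], ".",
                       attr_str(gid, tid), sep = "\t"),
                 paste(te$chrom, "sim", "exon", te$start, te$end, ".",
                       te$strand, ".", attr_str(gid, tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.adjacent_introns <- function(annotation, side, chrom, strand, pos) {
  ii <- annotation$introns
  sel <- if (side == "donor") ii$donor_pos == pos else ii$acceptor_pos == pos
  unique(ii[sel & ii$chrom == chrom & ii$strand == strand,
            .(chrom, intron_start, intron_end)])
}

#' Plant ground-truth NCL events on a simulated annotation
#'
#' Circular and intragenic trans-spliced events place the acceptor at or
#' upstream (in transcript direction) of the donor within one gene; fusion
#' events join boundaries of two genes. All junctions sit exactly at
#' annotated boundaries, every event uses boundaries (and adjacent introns)
#' no other event touches, donors keep an outgoing annotated intron and
#' acceptors an incoming one, so planted junction-read counts are
#' recoverable without interference. Trans events additionally get planted
#' out-of-circle mate pairs.
#'
#' @param config An `ncl_sim_config`.
#' @param annotation `ncl_annotation` built from the simulated GTF.
#' @return GroundTruth data.table: one row per planted event with key
#'   fields, class, intended ambiguity status and true counts.
#' @export
plant_events <- function(config, annotation) {
  set.seed(config$seed + 1L)
  ex <- annotation$exons
  t1 <- ex[grepl("\\.t1$", transcript_id)]
  kk <- t1[, .(k = .N, gene_id = gene_id[1L], chrom = chrom[1L],
               strand = strand[1L]), by = transcript_id]

  ## fast lookups: boundary positions per (transcript, rank) and adjacent
  ## intron claim-keys per boundary
  bkey <- paste(t1$transcript_id, t1$exon_rank)
  donor_of <- setNames(fifelse(t1$strand == "+", t1$end, t1$start), bkey)
  acceptor_of <- setNames(fifelse(t1$strand == "+", t1$start, t1$end), bkey)
  ii <- annotation$introns
  istr <- paste("I", ii$chrom, ii$intron_start, ii$intron_end, sep = "|")
  dmap <- lapply(split(istr, paste(ii$chrom, ii$strand, ii$donor_pos)),
                 unique)
  amap <- lapply(split(istr, paste(ii$chrom, ii$strand, ii$acceptor_pos)),
                 unique)

  used <- new.env(parent = emptyenv())
  claim <- function(keys) {
    if (any(vapply(keys, function(k) !is.null(used[[k]]), logical(1))))
      return(FALSE)
    for (k in keys) used[[k]] <- TRUE
    TRUE
  }
  try_event <- function(tx, ja, jd, gene_d, gene_a, chrom_d, strand_d,
                        chrom_a = chrom_d, strand_a = strand_d, tx_a = tx) {
    dp <- donor_of[[paste(tx, jd)]]
    ap <- acceptor_of[[paste(tx_a, ja)]]
    ik_d <- dmap[[paste(chrom_d, strand_d, dp)]]
    ik_a <- amap[[paste(chrom_a, strand_a, ap)]]
    if (is.null(ik_d) || is.null(ik_a)) return(NULL)
    keys <- c(paste("D", chrom_d, strand_d, dp, sep = "|"),
              paste("A", chrom_a, strand_a, ap, sep = "|"), ik_d, ik_a)
    if (!claim(keys)) return(NULL)
    list(donor_chrom = chrom_d, donor_pos = dp, donor_strand = strand_d,
         acceptor_chrom = chrom_a, acceptor_pos = ap,
         acceptor_strand = strand_a, gene_donor = gene_d,
         gene_acceptor = gene_a, transcript = tx)
  }

  ## intragenic candidates: (tx, ja <= jd), both interior enough to keep
  ## an incoming/outgoing intron
  cand <- rbindlist(lapply(seq_len(nrow(kk)), function(i) {
    k <- kk$k[i]
    if (k < 4L) return(NULL)
    grid <- CJ(ja = 2:(k - 1L), jd = 2:(k - 1L))[ja <= jd]
    grid[, `:=`(transcript_id = kk$transcript_id[i], gene_id = kk$gene_id[i],
                chrom = kk$chrom[i], strand = kk$strand[i])]
  }))
  cand <- as.list(cand[sample(.N)])
  n_intra <- config$n_circ + config$n_trans
  intra <- list()
  ci <- 1L
  while (length(intra) < n_intra && ci <= length(cand$ja)) {
    ev <- try_event(cand$transcript_id[ci], cand$ja[ci], cand$jd[ci],
                    cand$gene_id[ci], cand$gene_id[ci], cand$chrom[ci],
                    cand$strand[ci])
    if (!is.null(ev)) intra[[length(intra) + 1L]] <- ev
    ci <- ci + 1L
  }
  if (length(intra) < n_intra)
    stop("not enough exons for requested intragenic events")

  ## fusion candidates: donor of one gene, acceptor of another
  dopt <- rbindlist(lapply(seq_len(nrow(kk)), function(i)
    data.table(transcript_id = kk$transcript_id[i], rank = 1:(kk$k[i] - 1L),
               gene_id = kk$gene_id[i], chrom = kk$chrom[i],
               strand = kk$strand[i])))
  aopt <- rbindlist(lapply(seq_len(nrow(kk)), function(i)
    data.table(transcript_id = kk$transcript_id[i], rank = 2:kk$k[i],
               gene_id = kk$gene_id[i], chrom = kk$chrom[i],
               strand = kk$strand[i])))
  dopt <- as.list(dopt[sample(.N)])
  aopt <- as.list(aopt[sample(.N)])
  fusion <- list()
  di <- 1L
  while (length(fusion) < config$n_fusion && di <= length(dopt$rank)) {
    for (ai in seq_along(aopt$rank)) {
      if (aopt$gene_id[ai] == dopt$gene_id[di]) next
      ev <- try_event(dopt$transcript_id[di], aopt$rank[ai], dopt$rank[di],
                      dopt$gene_id[di], aopt$gene_id[ai], dopt$chrom[di],
                      dopt$strand[di], aopt$chrom[ai], aopt$strand[ai],
                      tx_a = aopt$transcript_id[ai])
      if (!is.null(ev)) {
        fusion[[length(fusion) + 1L]] <- ev
        break
      }
    }
    di <- di + 1L
  }
  if (length(fusion) < config$n_fusion)
    stop("not enough exons for requested fusion events")

  intra_dt <- rbindlist(intra)
  classes <- c(rep("circ", config$n_circ), rep("trans", config$n_trans))
  truth <- rbind(cbind(intra_dt, class = classes),
                 if (config$n_fusion > 0L)
                   cbind(rbindlist(fusion), class = "fusion"))
  truth[, event_id := sprintf("ev%03d", seq_len(.N))]
  truth[, key := .event_key(donor_chrom, donor_pos, donor_strand,
                            acceptor_chrom, acceptor_pos, acceptor_strand)]
  nE <- nrow(truth)
  truth[, intended_status := sample(c(
    rep("alt_colinear", config$n_alt_colinear),
    rep("multi_hit", config$n_multihit),
    rep("ok", nE - config$n_alt_colinear - config$n_multihit)))]
  truth[, n_ncl_true := pmax(1L, as.integer(round(rlnorm(nE, log(15),
                                                         0.7))))]
  truth[, n_d_true := sample(5:60, nE, replace = TRUE)]
  truth[, n_a_true := sample(5:60, nE, replace = TRUE)]
  truth[, out_pairs_true := fifelse(class == "trans",
                                    sample(1:5, nE, replace = TRUE), 0L)]
  truth[]
}

#' Emit per-tool detection tables from ground truth
#'
#' Each tool detects each event with `detection_prob` (every event is
#' forced to keep at least one detector, or it would vanish from the
#' union); reported counts are the true counts under multiplicative
#' log-normal noise floored at 1; a fraction of emitted records get up to
#' `jitter_max` bp of coordinate jitter to exercise snapping.
#'
#' @param truth GroundTruth table from [plant_events()].
#' @param config `ncl_sim_config`.
#' @param out_dir Directory receiving `tools/<tool>.tsv`.
#' @return list(tool_configs, reported) where `reported` is a long
#'   data.table (event_id, tool, n_ncl) of the emitted counts.
#' @export
emit_tool_reports <- function(truth, config, out_dir) {
  set.seed(config$seed + 2L)
  dir.create(file.path(out_dir, "tools"), recursive = TRUE,
             showWarnings = FALSE)
  nE <- nrow(truth)
  nT <- length(config$tools)
  U <- matrix(runif(nE * nT), nE, nT)
  det <- U < config$detection_prob
  none <- which(rowSums(det) == 0L)
  for (i in none) det[i, which.min(U[i, ])] <- TRUE
  reported <- list()
  tool_configs <- list()
  for (t in seq_len(nT)) {
    tool <- config$tools[t]
    idx <- which(det[, t])
    cnt <- truth$n_ncl_true[idx]
    if (config$dispersion > 0)
      cnt <- pmax(1L, as.integer(round(cnt * exp(rnorm(length(idx), 0,
                                                       config$dispersion)))))
    rec <- truth[idx, .(donor_chrom, donor_pos, donor_strand,
                        acceptor_chrom, acceptor_pos, acceptor_strand)]
    rec[, n_ncl := cnt]
    if (config$jitter_frac > 0 && config$jitter_max > 0L) {
      jit <- runif(length(idx)) < config$jitter_frac
      offs <- function(n) sample(c(-config$jitter_max:-1, 1:config$jitter_max),
                                 n, replace = TRUE)
      nj <- sum(jit)
      if (nj) {
        rec[jit, donor_pos := donor_pos + offs(nj)]
        rec[jit, acceptor_pos := acceptor_pos + offs(nj)]
      }
    }
    path <- file.path(out_dir, "tools", paste0(tool, ".tsv"))
    write_tool_events(rec, path)
    tool_configs[[tool]] <- canonical_tool_config(tool, path)
    reported[[tool]] <- data.table(event_id = truth$event_id[idx],
                                   tool = tool, n_ncl = cnt)
  }
  list(tool_configs = tool_configs, reported = rbindlist(reported))
}

.psl_row <- function(qname, qsize, qstart, qend, tname, tsize, tstart,
                     matches, mismatches = 0L, strand = "+") {
  span <- qend - qstart
  data.table(matches = matches, misMatches = mismatches, repMatches = 0L,
             nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
             tNumInsert = 0L, tBaseInsert = 0L, strand = strand,
             qName = qname, qSize = qsize, qStart = qstart, qEnd = qend,
             tName = tname, tSize = tsize, tStart = tstart,
             tEnd = tstart + span, blockCount = 1L,
             blockSizes = paste0(span, ","),
             qStarts = paste0(qstart, ","),
             tStarts = paste0(tstart, ","))
}

#' Emit PSL alignment fixtures realizing the intended ambiguity classes
#'
#' Every event gets the split self-locus hit pair a genuine NCL junction
#' produces (one half-query hit at the donor locus, one at the acceptor
#' locus). Multi-hit events add two decoy-locus hits covering 60% of the
#' query with scores 2 apart (within the score gap, below the identity
#' threshold). Alternative co-linear events add a transcript-target hit
#' crossing the junction midpoint at 85% identity.
#'
#' @param truth GroundTruth table.
#' @param annotation `ncl_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param config `ncl_sim_config`.
#' @param out_dir Directory receiving `genome.psl` and `transcripts.psl`.
#' @return list(genome_psl, transcripts_psl, seqs).
#' @export
emit_alignment_fixtures <- function(truth, annotation, genome, config,
                                    out_dir) {
  set.seed(config$seed + 3L)
  seqs <- build_junction_sequences(truth, annotation, genome,
                                   flank = config$flank)
  chrom_sizes <- setNames(Biostrings::width(genome), names(genome))
  last_chrom <- names(genome)[length(genome)]
  last_len <- chrom_sizes[[last_chrom]]
  tx_len <- annotation$exons[, .(len = sum(end - start + 1L)),
                             by = transcript_id]
  grows <- list()
  trows <- list()
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i]
    sq <- seqs[key == ev$key][1L]
    L <- nchar(sq$sequence)
    d <- sq$donor_flank_len
    a <- sq$acceptor_flank_len
    ## self-locus split pair
    d_tstart <- if (ev$donor_strand == "+") ev$donor_pos - d
                else ev$donor_pos - 1L
    a_tstart <- if (ev$acceptor_strand == "+") ev$acceptor_pos - 1L
                else ev$acceptor_pos - a
    grows[[length(grows) + 1L]] <- rbind(
      .psl_row(ev$key, L, 0L, d, ev$donor_chrom,
               chrom_sizes[[ev$donor_chrom]], d_tstart, matches = d,
               strand = ev$donor_strand),
      .psl_row(ev$key, L, d, L, ev$acceptor_chrom,
               chrom_sizes[[ev$acceptor_chrom]], a_tstart, matches = a,
               strand = ev$acceptor_strand))
    if (ev$intended_status == "multi_hit") {
      covlen <- as.integer(ceiling(0.6 * L))
      grows[[length(grows) + 1L]] <- rbind(
        .psl_row(ev$key, L, 0L, covlen, last_chrom, last_len,
                 last_len - 5000L, matches = covlen),
        .psl_row(ev$key, L, 0L, covlen, last_chrom, last_len,
                 last_len - 3000L, matches = covlen - 1L,
                 mismatches = 1L))
    }
    if (ev$intended_status == "alt_colinear") {
      tid <- ev$transcript
      tsize <- max(tx_len[transcript_id == tid, len], L)
      m <- as.integer(round(0.85 * L))
      trows[[length(trows) + 1L]] <-
        .psl_row(ev$key, L, 0L, L, tid, tsize, 0L, matches = m,
                 mismatches = L - m)
    }
  }
  gpath <- file.path(out_dir, "genome.psl")
  tpath <- file.path(out_dir, "transcripts.psl")
  write_psl(rbindlist(grows), gpath)
  tp <- if (length(trows)) rbindlist(trows) else .empty_psl()
  write_psl(tp, tpath)
  list(genome_psl = gpath, transcripts_psl = tpath, seqs = seqs)
}

#' Emit splice-junction and chimeric-read evidence fixtures
#'
#' Every annotated intron gets a background unique-read count; the introns
#' adjacent to each planted donor/acceptor boundary are overwritten so the
#' side's total equals the planted N_D/N_A exactly. Chimeric records
#' realize the planted out-of-circle mate pairs (trans events) plus
#' inside-circle mates that must not be counted.
#'
#' @param truth GroundTruth table.
#' @param annotation `ncl_annotation`.
#' @param config `ncl_sim_config`.
#' @param out_dir Directory receiving `sj.tab` and `chimeric.junction`.
#' @return list(sj, chimeric) paths.
#' @export
emit_evidence_fixtures <- function(truth, annotation, config, out_dir) {
  set.seed(config$seed + 4L)
  iu <- unique(annotation$introns[, .(chrom, strand, intron_start,
                                      intron_end)],
               by = c("chrom", "intron_start", "intron_end"))
  setorder(iu, chrom, intron_start, intron_end)
  iu[, unique_read_count := sample(5:100, .N, replace = TRUE)]
  set_side <- function(side, chrom, strand, pos, n) {
    it <- .adjacent_introns(annotation, side, chrom, strand, pos)
    setorder(it, intron_start)
    for (j in seq_len(nrow(it)))
      iu[chrom == it$chrom[j] & intron_start == it$intron_start[j] &
           intron_end == it$intron_end[j],
         unique_read_count := if (j == 1L) n else 0L]
  }
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i]
    set_side("donor", ev$donor_chrom, ev$donor_strand, ev$donor_pos,
             ev$n_d_true)
    set_side("acceptor", ev$acceptor_chrom, ev$acceptor_strand,
             ev$acceptor_pos, ev$n_a_true)
  }
  sj_path <- file.path(out_dir, "sj.tab")
  write_sj_counts(iu[, .(chrom, intron_start, intron_end, strand,
                         unique_read_count)], sj_path)

  chim <- list()
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i]
    base <- data.table(donor_chrom = ev$donor_chrom,
                       donor_pos = ev$donor_pos,
                       donor_strand = ev$donor_strand,
                       acceptor_chrom = ev$acceptor_chrom,
                       acceptor_pos = ev$acceptor_pos,
                       acceptor_strand = ev$acceptor_strand)
    if (ev$class %in% c("circ", "trans")) {
      cmin <- min(ev$donor_pos, ev$acceptor_pos)
      cmax <- max(ev$donor_pos, ev$acceptor_pos)
      inside <- cbind(base[rep(1L, 2L)],
                      data.table(read_id = sprintf("%s_in%d", ev$event_id,
                                                   1:2),
                                 mate_chrom = ev$donor_chrom,
                                 mate_start = cmin + 5L,
                                 mate_end = cmin + 54L))
      chim[[length(chim) + 1L]] <- inside
      if (ev$out_pairs_true > 0L) {
        j <- seq_len(ev$out_pairs_true)
        chim[[length(chim) + 1L]] <-
          cbind(base[rep(1L, ev$out_pairs_true)],
                data.table(read_id = sprintf("%s_out%d", ev$event_id, j),
                           mate_chrom = ev$donor_chrom,
                           mate_start = cmax + 101L + (j - 1L) * 10L,
                           mate_end = cmax + 200L + (j - 1L) * 10L))
      }
    } else {
      chim[[length(chim) + 1L]] <-
        cbind(base, data.table(read_id = paste0(ev$event_id, "_sup1"),
                               mate_chrom = ev$acceptor_chrom,
                               mate_start = ev$acceptor_pos + 5L,
                               mate_end = ev$acceptor_pos + 104L))
    }
  }
  chim_path <- file.path(out_dir, "chimeric.junction")
  write_chimeric(rbindlist(chim), chim_path)
  list(sj = sj_path, chimeric = chim_path)
}

#' Generate a complete synthetic fixture tree with ground truth
#'
#' Writes genome FASTA, GTF, per-tool event tables, genome/transcript PSL,
#' SJ and chimeric evidence, SCE BED, gene quantification, a manifest
#' (TSV + JSON) and a ready-to-run YAML config. Byte-deterministic for a
#' fixed seed.
#'
#' @param config `ncl_sim_config`.
#' @param out_dir Fixture directory (created).
#' @return list(config, truth, reported, run_config, paths, annotation).
#' @export
simulate_ncl_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "ncl_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  fasta <- file.path(out_dir, "genome.fa")
  gtf <- file.path(out_dir, "annotation.gtf")
  .write_genome_fasta(ref$genome, fasta)
  .write_gtf(copy(ref$exons), gtf)
  annotation <- read_annotation(gtf)

  truth <- plant_events(config, annotation)
  reports <- emit_tool_reports(truth, config, out_dir)
  aln <- emit_alignment_fixtures(truth, annotation, ref$genome, config,
                                 out_dir)
  evid <- emit_evidence_fixtures(truth, annotation, config, out_dir)

  set.seed(config$seed + 5L)
  ## SCE intervals over the first n_sce donor boundaries
  sce_path <- file.path(out_dir, "sce.bed")
  ns <- min(config$n_sce, nrow(truth))
  sce <- truth[seq_len(ns),
               .(chrom = donor_chrom, start = pmax(0L, donor_pos - 21L),
                 end = donor_pos + 20L)]
  fwrite(sce, sce_path, sep = "\t", col.names = FALSE, quote = FALSE)
  ## per-gene quantification, RSEM-style columns
  quant_path <- file.path(out_dir, "quant.tsv")
  genes <- annotation$genes[order(gene_id)]
  quant <- data.table(gene_id = genes$gene_id,
                      `transcript_id(s)` = paste0(genes$gene_id, ".t1"),
                      length = genes$end - genes$start + 1L,
                      effective_length = genes$end - genes$start + 1L,
                      expected_count = round(rlnorm(nrow(genes), 5, 1), 2),
                      TPM = round(rlnorm(nrow(genes), 2, 1), 2),
                      FPKM = round(rlnorm(nrow(genes), 2, 1), 2))
  fwrite(quant, quant_path, sep = "\t", quote = FALSE)

  manifest <- merge(truth,
                    dcast(reports$reported, event_id ~ tool,
                          value.var = "n_ncl"),
                    by = "event_id", all.x = TRUE)
  setnames(manifest, config$tools, paste0("n_ncl.", config$tools),
           skip_absent = TRUE)
  setorder(manifest, event_id)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  fwrite(manifest, manifest_path, sep = "\t", quote = FALSE, na = "NA")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", na = "null", digits = NA)

  run_config <- ncl_run_config(
    tools = unname(reports$tool_configs), gtf = gtf, genome = fasta,
    psl_genome = aln$genome_psl, psl_transcripts = aln$transcripts_psl,
    sj = evid$sj, chimeric = evid$chimeric,
    total_raw_reads = config$total_raw_reads,
    total_mapped_reads = config$total_mapped_reads, sce_bed = sce_path,
    quant = quant_path)
  yaml::write_yaml(list(
    gtf = gtf, genome = fasta, psl_genome = aln$genome_psl,
    psl_transcripts = aln$transcripts_psl, sj = evid$sj,
    chimeric = evid$chimeric, sce_bed = sce_path, quant = quant_path,
    total_raw_reads = config$total_raw_reads,
    total_mapped_reads = config$total_mapped_reads,
    tools = lapply(reports$tool_configs, function(tc)
      list(tool_name = tc$tool_name, path = tc$path,
           column_map = as.list(tc$column_map),
           coordinate_base = tc$coordinate_base, scope = tc$scope))),
    file.path(out_dir, "config.yaml"))

  list(config = config, truth = truth, reported = reports$reported,
       run_config = run_config, annotation = annotation,
       paths = list(out_dir = out_dir, genome = fasta, gtf = gtf,
                    manifest = manifest_path))
}
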