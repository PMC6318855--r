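## Readers/writers for every external format the pipeline touches.
## All coordinates are normalized to 1-based inclusive at this boundary;
## donor_pos is the last exonic base of the donor side and acceptor_pos the
## first exonic base of the acceptor side, both as genomic positions with a
## strand flag.

.ncl_roles <- c("donor_chrom", "donor_pos", "donor_strand",
                "acceptor_chrom", "acceptor_pos", "acceptor_strand", "n_ncl")

#' Describe one detector's event table
#'
#' Detector outputs differ in column order and coordinate convention; a
#' `ToolConfig` maps them declaratively onto the internal record instead of
#' needing one parser per tool.
#'
#' @param tool_name Label used in all downstream per-tool columns.
#' @param path Tab-delimited event table for this tool.
#' @param column_map Named vector/list mapping the seven roles
#'   `donor_chrom, donor_pos, donor_strand, acceptor_chrom, acceptor_pos,
#'   acceptor_strand, n_ncl` to (distinct) 1-based column indices.
#' @param coordinate_base 0 or 1. For 0-based inputs each position field is
#'   declared start-like (shifted +1) or end-like (end-exclusive, i.e. already
#'   equal to the 1-based last base; no shift) via `donor_pos_kind` /
#'   `acceptor_pos_kind`.
#' @param has_header Whether the first row is a header.
#' @param donor_pos_kind,acceptor_pos_kind `"end"` or `"start"`; only
#'   consulted when `coordinate_base = 0`. Defaults reflect the usual
#'   BED-like convention: donor positions end-like, acceptor positions
#'   start-like.
#' @param scope Which locus class this detector reports: `"both"`,
#'   `"intragenic"` (e.g. circRNA-only tools) or `"intergenic"` (fusion
#'   tools). Determines the number of compared tools `n` per locus class.
#' @return An object of class `ncl_tool_config`.
#' @export
tool_config <- function(tool_name, path, column_map,
                        coordinate_base = 1L, has_header = FALSE,
                        donor_pos_kind = c("end", "start"),
                        acceptor_pos_kind = c("start", "end"),
                        scope = c("both", "intragenic", "intergenic")) {
  donor_pos_kind <- match.arg(donor_pos_kind)
  acceptor_pos_kind <- match.arg(acceptor_pos_kind)
  scope <- match.arg(scope)
  cm <- unlist(column_map)
  missing_roles <- setdiff(.ncl_roles, names(cm))
  if (length(missing_roles))
    stop("tool '", tool_name, "': column_map lacks roles: ",
         paste(missing_roles, collapse = ", "))
  cm <- vapply(cm[.ncl_roles], as.integer, integer(1))
  if (anyDuplicated(cm))
    stop("tool '", tool_name, "': roles must map to distinct columns")
  if (!as.integer(coordinate_base) %in% c(0L, 1L))
    stop("coordinate_base must be 0 or 1")
  structure(list(tool_name = tool_name, path = path, column_map = cm,
                 coordinate_base = as.integer(coordinate_base),
                 has_header = isTRUE(has_header),
                 donor_pos_kind = donor_pos_kind,
                 acceptor_pos_kind = acceptor_pos_kind, scope = scope),
            class = "ncl_tool_config")
}

#' Shorthand config for the package's own canonical 7-column dialect
#'
#' Columns: donor chrom/pos/strand, acceptor chrom/pos/strand, read count;
#' 1-based, no header. This is the dialect [write_tool_events()] emits.
#' @inheritParams tool_config
#' @export
canonical_tool_config <- function(tool_name, path, scope = "both") {
  tool_config(tool_name, path,
              column_map = c(donor_chrom = 1, donor_pos = 2, donor_strand = 3,
                             acceptor_chrom = 4, acceptor_pos = 5,
                             acceptor_strand = 6, n_ncl = 7),
              scope = scope)
}

.empty_records <- function() {
  data.table(donor_chrom = character(), donor_pos = integer(),
             donor_strand = character(), acceptor_chrom = character(),
             acceptor_pos = integer(), acceptor_strand = character(),
             n_ncl = integer())
}

#' Read one detector's NCL event table
#'
#' @param config An `ncl_tool_config`.
#' @return data.table with columns donor_chrom, donor_pos, donor_strand,
#'   acceptor_chrom, acceptor_pos, acceptor_strand, n_ncl; coordinates
#'   1-based inclusive.
#' @export
read_tool_events <- function(config) {
  stopifnot(inherits(config, "ncl_tool_config"))
  if (!file.exists(config$path))
    stop("tool '", config$tool_name, "': file not found: ", config$path)
  dt <- fread(config$path, header = config$has_header, sep = "\t",
              colClasses = "character", fill = TRUE, na.strings = NULL)
  if (!nrow(dt)) return(.empty_records())
  cm <- config$column_map
  if (ncol(dt) < max(cm))
    stop("tool '", config$tool_name, "': table has ", ncol(dt),
         " columns but column_map needs column ", max(cm))
  get_col <- function(role) dt[[cm[[role]]]]
  blank <- Reduce(`|`, lapply(.ncl_roles, function(r) {
    x <- get_col(r); is.na(x) | x == ""
  }))
  if (any(blank))
    stop("tool '", config$tool_name, "': row ", which(blank)[1],
         " is missing a mapped column")
  parse_int <- function(role) {
    x <- get_col(role)
    bad <- !grepl("^[0-9]+$", x)
    if (any(bad))
      stop("tool '", config$tool_name, "': row ", which(bad)[1],
           ": non-integer value '", x[bad][1], "' in ", role)
    as.integer(x)
  }
  out <- data.table(
    donor_chrom = get_col("donor_chrom"),
    donor_pos = parse_int("donor_pos"),
    donor_strand = get_col("donor_strand"),
    acceptor_chrom = get_col("acceptor_chrom"),
    acceptor_pos = parse_int("acceptor_pos"),
    acceptor_strand = get_col("acceptor_strand"),
    n_ncl = parse_int("n_ncl"))
  if (config$coordinate_base == 0L) {
    if (config$donor_pos_kind == "start") out[, donor_pos := donor_pos + 1L]
    if (config$acceptor_pos_kind == "start")
      out[, acceptor_pos := acceptor_pos + 1L]
  }
  bad_strand <- !(out$donor_strand %in% c("+", "-")) |
    !(out$acceptor_strand %in% c("+", "-"))
  if (any(bad_strand))
    stop("tool '", config$tool_name, "': row ", which(bad_strand)[1],
         ": strand must be '+' or '-'")
  if (any(out$donor_pos < 1L) || any(out$acceptor_pos < 1L))
    stop("tool '", config$tool_name, "': positions must be >= 1")
  out[]
}

#' Write event records in the canonical 7-column dialect
#' @param records data.table as returned by [read_tool_events()].
#' @param path Output path.
#' @export
write_tool_events <- function(records, path) {
  fwrite(records[, .(donor_chrom, donor_pos, donor_strand, acceptor_chrom,
                     acceptor_pos, acceptor_strand, n_ncl)],
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Index a GTF annotation for junction snapping and intron lookup
#'
#' Builds, from the exon features of a GTF, the donor-boundary index
#' (transcript-direction exon ends), the acceptor-boundary index
#' (transcript-direction exon starts) and the intron table used for
#' co-linear junction-read counting. Boundaries are stored as genomic
#' positions plus a strand flag; donor/acceptor roles are defined in
#' transcript direction, so on the minus strand a donor boundary is the
#' genomic start of its exon.
#'
#' @param gtf_path GTF file with exon features carrying
#'   `gene_id`/`transcript_id` attributes (Ensembl/GENCODE dialect).
#' @return An object of class `ncl_annotation`: a list with data.tables
#'   `exons`, `genes`, `donors`, `acceptors`, `introns` and the chromosome
#'   set `chroms`.
#' @export
read_annotation <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- as.data.table(gr)
  if (!nrow(ex) || !any(ex$type == "exon"))
    stop("annotation contains no exon features: ", gtf_path)
  ex <- ex[type == "exon"]
  if (is.null(ex$transcript_id)) ex[, transcript_id := NA_character_]
  n_orphan <- sum(is.na(ex$transcript_id))
  if (n_orphan) {
    warning("skipping ", n_orphan, " exon(s) without transcript_id")
    ex <- ex[!is.na(transcript_id)]
  }
  if (!nrow(ex)) stop("no usable exon features in ", gtf_path)
  if (is.null(ex$gene_name)) ex[, gene_name := gene_id]
  ex[is.na(gene_name), gene_name := gene_id]
  exons <- ex[, .(chrom = as.character(seqnames), start, end,
                  strand = as.character(strand), gene_id, gene_name,
                  transcript_id)]
  if (any(exons$start > exons$end)) stop("exon with start > end")
  setorder(exons, transcript_id, start)
  exons[, exon_rank := if (strand[1L] == "-") rev(seq_len(.N))
        else seq_len(.N), by = transcript_id]
  ## per-transcript exons must not overlap
  ov <- exons[, .(bad = .N > 1L && any(start[-1L] <= end[-.N])),
              by = transcript_id]
  if (any(ov$bad))
    stop("overlapping exons within transcript(s): ",
         paste(head(ov[bad == TRUE, transcript_id], 3), collapse = ", "))

  donors <- exons[, .(chrom, strand,
                      pos = fifelse(strand == "+", end, start),
                      gene_id, transcript_id, exon_rank)]
  acceptors <- exons[, .(chrom, strand,
                         pos = fifelse(strand == "+", start, end),
                         gene_id, transcript_id, exon_rank)]
  setkey(donors, chrom, strand, pos)
  setkey(acceptors, chrom, strand, pos)

  introns <- exons[, if (.N > 1L) .(
    chrom = chrom[-1L],
    strand = strand[-1L],
    intron_start = end[-.N] + 1L,
    intron_end = start[-1L] - 1L,
    gene_id = gene_id[-1L]
  ), by = transcript_id]
  if (nrow(introns)) {
    introns[, donor_pos := fifelse(strand == "+", intron_start - 1L,
                                   intron_end + 1L)]
    introns[, acceptor_pos := fifelse(strand == "+", intron_end + 1L,
                                      intron_start - 1L)]
  } else {
    introns <- data.table(transcript_id = character(), chrom = character(),
                          strand = character(), intron_start = integer(),
                          intron_end = integer(), gene_id = character(),
                          donor_pos = integer(), acceptor_pos = integer())
  }
  genes <- exons[, .(gene_name = gene_name[1L], chrom = chrom[1L],
                     strand = strand[1L], start = min(start),
                     end = max(end)), by = gene_id]
  tx_exons <- split(exons, by = "transcript_id")
  tx_exons <- lapply(tx_exons, function(te) te[order(exon_rank)])
  structure(list(exons = exons, genes = genes, donors = donors,
                 acceptors = acceptors, introns = introns,
                 tx_exons = tx_exons, chroms = unique(exons$chrom)),
            class = "ncl_annotation")
}

#' @export
print.ncl_annotation <- function(x, ...) {
  cat("ncl_annotation:", nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$exons), "exons on", length(x$chroms), "chromosome(s)\n")
  invisible(x)
}

.psl_cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
               "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
               "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
               "blockCount", "blockSizes", "qStarts", "tStarts")

.empty_psl <- function() {
  out <- data.table(matches = integer(), misMatches = integer(),
                    repMatches = integer(), nCount = integer(),
                    qNumInsert = integer(), qBaseInsert = integer(),
                    tNumInsert = integer(), tBaseInsert = integer(),
                    strand = character(), qName = character(),
                    qSize = integer(), qStart = integer(), qEnd = integer(),
                    tName = character(), tSize = integer(),
                    tStart = integer(), tEnd = integer(),
                    blockCount = integer(), blockSizes = character(),
                    qStarts = character(), tStarts = character())
  out
}

#' Read a BLAT PSL alignment file
#'
#' Accepts files with or without the 5-line psLayout header. Query/target
#' coordinates keep the native PSL convention (0-based half-open).
#'
#' @param path PSL file.
#' @return data.table with the 21 PSL columns; block lists are kept as the
#'   native comma-terminated strings (see [psl_block_list()]).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1L], "psLayout")) {
    if (length(lines) < 5L) stop("truncated psLayout header in ", path)
    lines <- lines[-seq_len(5L)]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_psl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    bad <- which(nf != 21L)[1L]
    stop("PSL line ", bad, ": expected 21 columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  int_cols <- c(1:8, 11:13, 15:18)
  out <- as.data.table(setNames(lapply(seq_len(21L), function(i) {
    if (i %in% int_cols) as.integer(m[, i]) else m[, i]
  }), .psl_cols))
  bad <- out$qStart >= out$qEnd | out$qEnd > out$qSize
  if (any(bad))
    stop("PSL line ", which(bad)[1L], ": requires qStart < qEnd <= qSize")
  for (col in c("blockSizes", "qStarts", "tStarts")) {
    n <- lengths(psl_block_list(out[[col]]))
    if (any(n != out$blockCount))
      stop("PSL line ", which(n != out$blockCount)[1L],
           ": ", col, " length disagrees with blockCount")
  }
  out
}

#' Parse PSL comma-terminated block lists into integer vectors
#' @param x Character vector of comma-separated (optionally comma-terminated)
#'   integer lists.
#' @export
psl_block_list <- function(x) {
  lapply(strsplit(sub(",+$", "", x), ",", fixed = TRUE), as.integer)
}

#' Write alignments as PSL
#' @param hits data.table with the 21 PSL columns.
#' @param path Output path.
#' @export
write_psl <- function(hits, path) {
  fwrite(hits[, .psl_cols, with = FALSE], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read splice-junction read counts (STAR SJ.out.tab dialect)
#'
#' Nine tab columns: chrom, intron start, intron end (1-based inclusive,
#' first/last intronic base), strand code (0 undetermined / 1 + / 2 -),
#' motif, annotated flag, unique-read count, multi-read count, max overhang.
#' Only the unique-read count is retained: multi-mapped junction reads are
#' excluded from all downstream counting.
#'
#' @param path SJ table.
#' @return data.table chrom, intron_start, intron_end, strand,
#'   unique_read_count.
#' @export
read_sj_counts <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (!nrow(dt))
    return(data.table(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      unique_read_count = integer()))
  if (ncol(dt) < 9L)
    stop("SJ table must have 9 columns, found ", ncol(dt))
  num_ok <- grepl("^[0-9]+$", dt[[2]]) & grepl("^[0-9]+$", dt[[3]]) &
    grepl("^[0-9]+$", dt[[7]]) & dt[[4]] %in% c("0", "1", "2")
  if (!all(num_ok))
    stop("malformed SJ row ", which(!num_ok)[1L])
  out <- data.table(chrom = dt[[1]],
                    intron_start = as.integer(dt[[2]]),
                    intron_end = as.integer(dt[[3]]),
                    strand = c(`0` = "undetermined", `1` = "+",
                               `2` = "-")[dt[[4]]],
                    unique_read_count = as.integer(dt[[7]]))
  if (any(out$intron_start > out$intron_end))
    stop("SJ row with intron_start > intron_end")
  out[]
}

#' Write splice-junction counts in the 9-column SJ dialect
#' @param sj data.table as from [read_sj_counts()].
#' @param path Output path.
#' @export
write_sj_counts <- function(sj, path) {
  code <- c(undetermined = 0L, `+` = 1L, `-` = 2L)[sj$strand]
  out <- data.table(sj$chrom, sj$intron_start, sj$intron_end, code,
                    0L, 1L, sj$unique_read_count, 0L, 50L)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

.cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(m)) stop("malformed CIGAR: ", cg)
    op <- substring(m, nchar(m))
    len <- as.integer(substring(m, 1L, nchar(m) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read chimeric junction-spanning read records (STAR-style dialect)
#'
#' Fourteen tab columns: donor chrom/pos/strand (1-3), acceptor
#' chrom/pos/strand (4-6), junction type, repeat lengths (7-9), read id
#' (10), junction-segment pos and CIGAR (11-12), mate pos and CIGAR
#' (13-14). The mate is taken to lie on the acceptor chromosome; its
#' interval end is derived from the CIGAR reference span.
#'
#' @param path Chimeric junction file.
#' @return data.table with junction key fields, read_id and the mate
#'   interval (1-based inclusive).
#' @export
read_chimeric <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (!nrow(dt))
    return(data.table(donor_chrom = character(), donor_pos = integer(),
                      donor_strand = character(),
                      acceptor_chrom = character(),
                      acceptor_pos = integer(),
                      acceptor_strand = character(), read_id = character(),
                      mate_chrom = character(), mate_start = integer(),
                      mate_end = integer()))
  if (ncol(dt) < 14L)
    stop("chimeric junction table must have 14 columns, found ", ncol(dt))
  ok <- grepl("^[0-9]+$", dt[[2]]) & grepl("^[0-9]+$", dt[[5]]) &
    grepl("^[0-9]+$", dt[[13]])
  if (!all(ok)) stop("malformed chimeric row ", which(!ok)[1L])
  mate_start <- as.integer(dt[[13]])
  out <- data.table(donor_chrom = dt[[1]], donor_pos = as.integer(dt[[2]]),
                    donor_strand = dt[[3]], acceptor_chrom = dt[[4]],
                    acceptor_pos = as.integer(dt[[5]]),
                    acceptor_strand = dt[[6]], read_id = dt[[10]],
                    mate_chrom = dt[[4]], mate_start = mate_start,
                    mate_end = mate_start + .cigar_ref_span(dt[[14]]) - 1L)
  if (any(out$donor_pos < 1L) || any(out$acceptor_pos < 1L) ||
      any(out$mate_start < 1L))
    stop("chimeric positions must be >= 1")
  out[]
}

#' Write chimeric records in the 14-column dialect
#' @param chim data.table as from [read_chimeric()].
#' @param path Output path.
#' @export
write_chimeric <- function(chim, path) {
  out <- data.table(chim$donor_chrom, chim$donor_pos, chim$donor_strand,
                    chim$acceptor_chrom, chim$acceptor_pos,
                    chim$acceptor_strand, 0L, -1L, -1L, chim$read_id,
                    chim$donor_pos, "50M", chim$mate_start,
                    paste0(chim$mate_end - chim$mate_start + 1L, "M"))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read SCE intervals (BED) and per-gene quantification (RSEM dialect)
#'
#' Both inputs are optional: `NULL` paths yield empty containers and the
#' corresponding report columns are emitted as `NA`.
#'
#' @param sce_bed_path BED file (0-based half-open) of synonymous constraint
#'   elements, or NULL.
#' @param quant_path Gene quantification table with `gene_id`, `TPM`, `FPKM`
#'   columns (RSEM `*.genes.results` works), or NULL.
#' @return list(sce = data.table(chrom, start, end) 1-based inclusive or
#'   NULL, quant = data.table(gene_id, tpm, fpkm) or NULL).
#' @export
read_auxiliary <- function(sce_bed_path = NULL, quant_path = NULL) {
  sce <- NULL
  if (!is.null(sce_bed_path)) {
    bed <- fread(sce_bed_path, header = FALSE, sep = "\t")
    if (nrow(bed)) {
      if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
      if (any(bed[[2]] < 0L) || any(bed[[3]] < 0L))
        stop("negative BED coordinate")
      sce <- data.table(chrom = as.character(bed[[1]]),
                        start = as.integer(bed[[2]]) + 1L,
                        end = as.integer(bed[[3]]))
    } else {
      sce <- data.table(chrom = character(), start = integer(),
                        end = integer())
    }
  }
  quant <- NULL
  if (!is.null(quant_path)) {
    q <- fread(quant_path, header = TRUE, sep = "\t")
    need <- c("gene_id", "TPM", "FPKM")
    if (!all(need %in% names(q)))
      stop("quantification table needs columns: ",
           paste(need, collapse = ", "))
    quant <- q[, .(gene_id = as.character(gene_id), tpm = as.numeric(TPM),
                   fpkm = as.numeric(FPKM))]
    if (any(quant$tpm < 0, na.rm = TRUE) || any(quant$fpkm < 0, na.rm = TRUE))
      stop("TPM/FPKM must be non-negative")
  }
  list(sce = sce, quant = quant)
}
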