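## In-code fixtures: a tiny deterministic annotation/genome pair, fabricated
## harmonized tables and PSL hits, and memoized full synthetic fixtures for
## the slower end-to-end tests.

library(data.table)

.gtf_attr <- function(g, t) {
  sprintf("gene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";", g, t, g)
}

.gtf_exon <- function(chrom, start, end, strand, g, t) {
  paste(chrom, "test", "exon", start, end, ".", strand, ".",
        .gtf_attr(g, t), sep = "\t")
}

## GA: + strand chr1, 4 exons; GB: - strand chr1, 3 exons; GC: + chr2
write_test_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    .gtf_exon("chr1", 100, 200, "+", "GA", "GA.t1"),
    .gtf_exon("chr1", 300, 400, "+", "GA", "GA.t1"),
    .gtf_exon("chr1", 500, 600, "+", "GA", "GA.t1"),
    .gtf_exon("chr1", 700, 800, "+", "GA", "GA.t1"),
    .gtf_exon("chr1", 1100, 1200, "-", "GB", "GB.t1"),
    .gtf_exon("chr1", 1300, 1400, "-", "GB", "GB.t1"),
    .gtf_exon("chr1", 1500, 1600, "-", "GB", "GB.t1"),
    .gtf_exon("chr2", 100, 250, "+", "GC", "GC.t1"),
    .gtf_exon("chr2", 400, 500, "+", "GC", "GC.t1"))
  writeLines(lines, path)
  path
}

test_annotation <- function() read_annotation(write_test_gtf())

test_genome <- function(len1 = 6000, len2 = 2000, seed = 99) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  Biostrings::DNAStringSet(c(chr1 = rnd(len1), chr2 = rnd(len2)))
}

## a harmonized-table stub: records already at annotated boundaries
fake_harmonized <- function(df) {
  dt <- as.data.table(df)
  if (is.null(dt$donor_chrom)) dt[, donor_chrom := "chr1"]
  if (is.null(dt$acceptor_chrom)) dt[, acceptor_chrom := "chr1"]
  if (is.null(dt$donor_strand)) dt[, donor_strand := "+"]
  if (is.null(dt$acceptor_strand)) dt[, acceptor_strand := "+"]
  if (is.null(dt$donor_genes)) dt[, donor_genes := "GA"]
  if (is.null(dt$acceptor_genes)) dt[, acceptor_genes := "GA"]
  if (is.null(dt$locus_class)) dt[, locus_class := "intragenic"]
  dt[, `:=`(raw_donor_pos = donor_pos, raw_acceptor_pos = acceptor_pos,
            status = "ok")]
  dt[, key := sprintf("%s:%d:%s|%s:%d:%s", donor_chrom, donor_pos,
                      donor_strand, acceptor_chrom, acceptor_pos,
                      acceptor_strand)]
  dt
}

## one fabricated PSL hit (21 columns), single block
psl_hit <- function(qName = "q", qSize = 200L, qStart = 0L, qEnd = 200L,
                    tName = "chr1", tStart = 0L, matches = qEnd - qStart,
                    misMatches = 0L, repMatches = 0L, qNumInsert = 0L,
                    tNumInsert = 0L, tSize = 100000L, strand = "+",
                    source = NULL) {
  dt <- data.table(
    matches = as.integer(matches), misMatches = as.integer(misMatches),
    repMatches = as.integer(repMatches), nCount = 0L,
    qNumInsert = as.integer(qNumInsert), qBaseInsert = 0L,
    tNumInsert = as.integer(tNumInsert), tBaseInsert = 0L,
    strand = strand, qName = qName, qSize = as.integer(qSize),
    qStart = as.integer(qStart), qEnd = as.integer(qEnd), tName = tName,
    tSize = as.integer(tSize), tStart = as.integer(tStart),
    tEnd = as.integer(tStart + (qEnd - qStart)), blockCount = 1L,
    blockSizes = paste0(qEnd - qStart, ","),
    qStarts = paste0(qStart, ","), tStarts = paste0(tStart, ","))
  if (!is.null(source)) dt[, source := source]
  dt
}

## memoized full fixtures (built once per test file)
.fx_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fx_cache$default)) {
    dir <- file.path(tempdir(), "ncl_fixture_default")
    fx <- simulate_ncl_fixture(sim_config(seed = 42L), dir)
    res <- suppressWarnings(ncl_screen(fx$run_config))
    .fx_cache$default <- list(fx = fx, res = res)
  }
  .fx_cache$default
}

noiseless_fixture <- function() {
  if (is.null(.fx_cache$noiseless)) {
    dir <- file.path(tempdir(), "ncl_fixture_noiseless")
    cfg <- sim_config(seed = 43L, detection_prob = 1, dispersion = 0,
                      jitter_frac = 0)
    fx <- simulate_ncl_fixture(cfg, dir)
    res <- suppressWarnings(ncl_screen(fx$run_config))
    .fx_cache$noiseless <- list(fx = fx, res = res)
  }
  .fx_cache$noiseless
}
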