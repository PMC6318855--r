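## annotation for spliced-flank construction: one + gene with a short donor
## exon, and a single-exon gene for short-circle behaviour
write_flank_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    .gtf_exon("chr1", 4801, 4900, "+", "GF", "GF.t1"),   # 100 nt
    .gtf_exon("chr1", 4951, 5000, "+", "GF", "GF.t1"),   # 50 nt (donor exon)
    .gtf_exon("chr1", 5100, 5249, "+", "GF", "GF.t1"),   # 150 nt
    .gtf_exon("chr1", 300, 419, "+", "GS", "GS.t1"),     # 120 nt circle
    .gtf_exon("chr1", 1000, 1199, "-", "GM", "GM.t1"))   # 200 nt minus
  writeLines(lines, path)
  path
}

test_that("donor flank walks the spliced transcript across exon junctions", {
  ann <- read_annotation(write_flank_gtf())
  genome <- test_genome()
  ev <- list(donor_chrom = "chr1", donor_pos = 5000L, donor_strand = "+",
             acceptor_chrom = "chr1", acceptor_pos = 5100L,
             acceptor_strand = "+", key = "k1")
  js <- build_junction_sequence(ev, ann, genome, flank = 100L)
  g <- function(a, b) as.character(Biostrings::subseq(genome[["chr1"]], a, b))
  expect_equal(js$donor_flank_len, 100L)
  expect_equal(substr(js$sequence, 1, 100),
               paste0(g(4851, 4900), g(4951, 5000)))
  expect_equal(substr(js$sequence, 101, 200), g(5100, 5199))
  expect_equal(js$acceptor_flank_len, 100L)
  expect_equal(nchar(js$sequence), 200L)
})

test_that("a 120 nt exonic circle yields a 120 nt sequence covering it once", {
  ann <- read_annotation(write_flank_gtf())
  genome <- test_genome()
  ev <- list(donor_chrom = "chr1", donor_pos = 419L, donor_strand = "+",
             acceptor_chrom = "chr1", acceptor_pos = 300L,
             acceptor_strand = "+", key = "k2")
  js <- build_junction_sequence(ev, ann, genome, flank = 100L)
  expect_equal(nchar(js$sequence), 120L)
  expect_equal(js$donor_flank_len + js$acceptor_flank_len, 120L)
  g <- function(a, b) as.character(Biostrings::subseq(genome[["chr1"]], a, b))
  circ <- g(300, 419)
  d <- js$donor_flank_len
  expect_equal(js$sequence,
               paste0(substr(circ, 120 - d + 1, 120),
                      substr(circ, 1, 120 - d)))
})

test_that("minus-strand flanks are reverse-complemented spliced sequence", {
  ann <- read_annotation(write_flank_gtf())
  genome <- test_genome()
  ## GM on -: donor boundary = genomic start 1000, acceptor = genomic end 1199
  ev <- list(donor_chrom = "chr1", donor_pos = 1000L, donor_strand = "-",
             acceptor_chrom = "chr1", acceptor_pos = 1199L,
             acceptor_strand = "-", key = "k3")
  js <- build_junction_sequence(ev, ann, genome, flank = 100L)
  rc <- function(a, b)
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[["chr1"]], a, b)))
  expect_equal(nchar(js$sequence), 200L)
  ## spliced(-) = rc(g[1000..1199]); donor flank = its last 100 = rc(g[1000..1099])
  expect_equal(substr(js$sequence, 1, 100), rc(1000, 1099))
  expect_equal(substr(js$sequence, 101, 200), rc(1100, 1199))
})

test_that("junction sequence length always equals the two flank lengths", {
  nf <- noiseless_fixture()
  seqs <- nf$res$seqs
  expect_true(all(nchar(seqs$sequence) ==
                    seqs$donor_flank_len + seqs$acceptor_flank_len))
  expect_true(all(nchar(seqs$sequence) <= 200L))
})

test_that("hit scoring follows the web-BLAT convention", {
  h <- psl_hit(qSize = 200, qStart = 0, qEnd = 200, matches = 190,
               misMatches = 5, qNumInsert = 1, tNumInsert = 1)
  sc <- score_hit(h)
  expect_equal(sc$score, 183)
  expect_equal(sc$identity, 0.95)
  sc2 <- score_hit(psl_hit(qSize = 200, matches = 200))
  expect_equal(sc2$score, 200)
  expect_equal(sc2$identity, 1.0)
  expect_error(score_hit(psl_hit(qSize = 0, qStart = 0, qEnd = 0,
                                 matches = 0)), "qSize")
})

test_that("alternative co-linear detection needs midpoint coverage and >80% identity", {
  js <- list(donor_flank_len = 100L)
  hit_ok <- psl_hit(qStart = 0, qEnd = 200, matches = 165)   # identity 0.825
  expect_false(is.null(find_alt_colinear(hit_ok, js)))
  ## does not cross the midpoint
  hit_half <- psl_hit(qStart = 0, qEnd = 95, matches = 95)
  expect_null(find_alt_colinear(hit_half, js))
  ## crosses but below threshold (identity 0.79)
  hit_low <- psl_hit(qStart = 0, qEnd = 200, matches = 158)
  expect_null(find_alt_colinear(hit_low, js))
  ## identity exactly 0.80 is NOT above the threshold
  hit_edge <- psl_hit(qStart = 0, qEnd = 200, matches = 160)
  expect_null(find_alt_colinear(hit_edge, js))
  ## insufficient margin around the midpoint
  hit_margin <- psl_hit(qStart = 95, qEnd = 200, matches = 105)
  expect_null(find_alt_colinear(hit_margin, js))
})

test_that("multi-hit needs two distinct loci within the score gap", {
  two <- rbind(psl_hit(tName = "chr1", tStart = 0, qEnd = 200,
                       matches = 183),
               psl_hit(tName = "chr2", tStart = 0, qEnd = 200,
                       matches = 181))
  sc <- score_hit(two)
  expect_equal(sc$score, c(183, 181))
  expect_true(as.logical(find_multi_hit(two)))         # gap 2 < 3
  far <- rbind(psl_hit(tName = "chr1", tStart = 0, qEnd = 200,
                       matches = 183),
               psl_hit(tName = "chr2", tStart = 0, qEnd = 200,
                       matches = 179))
  expect_false(as.logical(find_multi_hit(far)))        # gap 4
  ## duplicate lines at the identical interval are one locus
  dupl <- rbind(psl_hit(tName = "chr1", tStart = 500, qEnd = 200),
                psl_hit(tName = "chr1", tStart = 500, qEnd = 200))
  expect_false(as.logical(find_multi_hit(dupl)))
  ## the event's own split pair collapses to one locus
  self_iv <- data.table(chrom = "chr1", start = c(900L, 2000L),
                        end = c(1100L, 2200L))
  selfpair <- rbind(psl_hit(tStart = 950, qStart = 0, qEnd = 100,
                            matches = 100, qSize = 200),
                    psl_hit(tStart = 2050, qStart = 100, qEnd = 200,
                            matches = 100, qSize = 200))
  expect_false(as.logical(find_multi_hit(selfpair,
                                         self_intervals = self_iv)))
  ## low-coverage hits define no locus
  short <- rbind(psl_hit(tName = "chr1", qStart = 0, qEnd = 90,
                         matches = 90),
                 psl_hit(tName = "chr2", qStart = 0, qEnd = 90,
                         matches = 89, misMatches = 1))
  expect_false(as.logical(find_multi_hit(short)))
})

test_that("alt-colinear takes precedence and no hits fall back to ok", {
  ev <- list(key = "k")
  js <- list(donor_flank_len = 100L)
  both <- rbind(
    psl_hit(qName = "k", qStart = 0, qEnd = 200, matches = 190,
            misMatches = 10, tName = "chr3", tStart = 10,
            source = "genome"),
    psl_hit(qName = "k", qStart = 0, qEnd = 200, matches = 189,
            misMatches = 11, tName = "chr4", tStart = 10,
            source = "genome"))
  call <- classify_ambiguity(ev, both, js)
  expect_equal(call$status, "alt_colinear")
  expect_true(call$alt_colinear)
  expect_true(call$multi_hit)

  expect_warning(none <- classify_ambiguity(ev, both[0], js), "nowhere")
  expect_equal(none$status, "ok")
  expect_equal(none$best_hit_score, 0)
})

test_that("threshold monotonicity holds on the planted fixture", {
  df <- default_fixture()
  run_with <- function(identity_threshold = 0.80, score_gap = 3) {
    hits <- rbind(
      read_psl(df$fx$run_config$psl_genome)[, source := "genome"],
      read_psl(df$fx$run_config$psl_transcripts)[, source := "transcript"])
    suppressWarnings(classify_events(
      df$res$events, hits, df$res$seqs,
      identity_threshold = identity_threshold, score_gap = score_gap))
  }
  base <- run_with()
  stricter_id <- run_with(identity_threshold = 0.90)
  expect_lte(sum(stricter_id$alt_colinear), sum(base$alt_colinear))
  wider_gap <- run_with(score_gap = 6)
  expect_gte(sum(wider_gap$multi_hit), sum(base$multi_hit))
  narrow_gap <- run_with(score_gap = 1)
  expect_lte(sum(narrow_gap$multi_hit), sum(base$multi_hit))
})
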