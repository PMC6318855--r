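test_that("tau reproduces hand-computed heterogeneity values", {
  expect_equal(compute_tau(c(7, 7, 7)), 0, tolerance = 1e-12)
  expect_equal(compute_tau(c(5, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(compute_tau(c(9, 9, 0)), 0.5, tolerance = 1e-12)
  expect_equal(compute_tau(c(3, 1)), 0.5, tolerance = 1e-12)
  expect_error(compute_tau(c(0, 0, 0)), "undefined")
  expect_warning(t1 <- compute_tau(5), "single-tool")
  expect_equal(t1, 0)
})

test_that("tau is log-base invariant, bounded, and pins its extremes", {
  set.seed(5)
  for (i in 1:300) {
    n <- sample(2:9, 1)
    x <- sample(0:40, n, replace = TRUE)
    if (all(x == 0)) x[1] <- 1L
    t_e <- compute_tau(x, log_base = exp(1))
    t_10 <- compute_tau(x, log_base = 10)
    expect_lt(abs(t_e - t_10), 1e-12)
    expect_gte(t_e, 0)
    expect_lte(t_e, 1)
    single <- sum(x > 0) == 1L
    expect_equal(t_e == 1, single)
    all_equal_pos <- length(unique(x)) == 1L && x[1] > 0
    expect_equal(abs(t_e) < 1e-12, all_equal_pos)
  }
})

test_that("the NCL score matches direct evaluation and is monotone", {
  expect_equal(compute_ncl_score(c(10, 10, 10), tau = 0), 4.000043,
               tolerance = 1e-5)
  expect_equal(compute_ncl_score(c(5, 0, 0), tau = 1), -2.004321,
               tolerance = 1e-5)
  expect_equal(compute_ncl_score(c(9, 9, 0)), 2.200975, tolerance = 1e-5)
  ## strictly increasing in the median at fixed tau
  for (tau in c(0, 0.3, 0.9)) {
    s <- vapply(1:25, function(m)
      compute_ncl_score(rep(m, 3), tau = tau), numeric(1))
    expect_true(all(diff(s) > 0))
  }
  ## strictly decreasing in tau at fixed median
  s2 <- vapply(seq(0, 1, by = 0.05), function(tau)
    compute_ncl_score(rep(8, 3), tau = tau), numeric(1))
  expect_true(all(diff(s2) < 0))
})

test_that("NCL ratio and circular fraction match hand arithmetic", {
  expect_equal(ncl_ratio(5, 5, 5), 0.5)
  expect_equal(ncl_ratio(10, 20, 20), 1 / 3)
  expect_equal(ncl_ratio(4, 0, 0), 1)
  expect_true(is.na(ncl_ratio(0, 0, 0)))
  expect_equal(circular_fraction(10, 20, 20), 10 / 51)
  expect_equal(circular_fraction(5, 5, 5), 0.3125)
  expect_equal(circular_fraction(0, 7, 9), 0)
  expect_error(ncl_ratio(-1, 0, 0), "non-negative")
})

test_that("R > 0.5 exactly when NCL junction reads outnumber co-linear ones", {
  grid <- CJ(n = 0:12, d = 0:12, a = 0:12)
  r <- ncl_ratio(grid$n, grid$d, grid$a)
  defined <- !is.na(r)
  expect_equal(r[defined] > 0.5,
               (2 * grid$n > grid$d + grid$a)[defined])
})

test_that("junction usage frequencies normalize within the host gene", {
  ju <- junction_usage(30, 0, c(10, 30, 60))
  expect_equal(ju$p_d, 0.3)
  expect_equal(ju$p_a, 0)
  expect_equal(ju$p_median_donor, 0.3)   # median of {0.1, 0.3, 0.6}
  ## single-junction gene
  ju1 <- junction_usage(100, 100, 100)
  expect_equal(ju1$p_d, 1)
  expect_equal(ju1$p_median_donor, 1)
  ## frequencies sum to one
  counts <- c(4, 16, 30, 50)
  expect_equal(sum(counts / sum(counts)), 1)
  ## zero totals yield missing values
  ju0 <- junction_usage(0, 0, integer())
  expect_true(is.na(ju0$p_d))
})

test_that("SCE flags are positional and NA without an SCE annotation", {
  ev <- data.table(donor_chrom = "chr1", donor_pos = c(150L, 201L),
                   donor_strand = "+", acceptor_chrom = "chr1",
                   acceptor_pos = c(150L, 500L), acceptor_strand = "+")
  ev[, key := paste0("k", 1:2)]
  sce <- data.table(chrom = "chr1", start = 100L, end = 200L)
  fl <- sce_flags(ev, sce)
  expect_equal(fl$sce_donor, c(TRUE, FALSE))
  expect_equal(fl$sce_acceptor, c(TRUE, FALSE))
  fl0 <- sce_flags(ev, NULL)
  expect_true(all(is.na(fl0$sce_donor)))
})

test_that("metrics rows wire counts, usage and expression context together", {
  ann <- test_annotation()
  rec <- data.table(donor_chrom = "chr1", donor_pos = 400L,
                    donor_strand = "+", acceptor_chrom = "chr1",
                    acceptor_pos = 100L, acceptor_strand = "+", n_ncl = 10L)
  recB <- copy(rec)[, n_ncl := 20L]
  harmonized <- list(toolA = harmonize_events(rec, ann),
                     toolB = harmonize_events(recB, ann))
  events <- merge_tool_reports(harmonized)
  sj <- data.table(chrom = "chr1",
                   intron_start = c(201L, 401L, 601L),
                   intron_end = c(299L, 499L, 699L), strand = "+",
                   unique_read_count = c(10L, 30L, 60L))
  evidence <- count_junction_reads(events, sj, ann)
  ## donor 400 feeds intron 401..499 (30); acceptor 100 has no incoming
  expect_equal(evidence$events$n_d, 30L)
  quant <- data.table(gene_id = "GA", tpm = 7.5, fpkm = 3.25)
  m <- compute_metrics(events, evidence,
                       tool_scopes = c(toolA = "both", toolB = "both"),
                       total_raw_reads = 1.5e7, total_mapped_reads = 1e7,
                       quant = quant)
  expect_equal(m$n_tools, 2L)
  expect_equal(m$n_ncl, 15)              # median of detected {10, 20}
  expect_equal(m$median_n_ncl, 15)
  expect_equal(m$tau_ncl, compute_tau(c(10, 20)))
  expect_equal(m$r_ncl, ncl_ratio(15, 30, 0))
  expect_equal(m$cf, circular_fraction(15, 30, 0))
  expect_equal(m$p_d, 0.3)
  expect_equal(m$p_median_donor, 0.3)
  expect_equal(m$rpm_raw, 1)
  expect_equal(m$rpm_mapped, 1.5)
  expect_equal(m$tpm, 7.5)
  expect_true(is.na(m$sce_donor))
})

test_that("tool scope fixes n per locus class", {
  ann <- test_annotation()
  intra <- data.table(donor_chrom = "chr1", donor_pos = 400L,
                      donor_strand = "+", acceptor_chrom = "chr1",
                      acceptor_pos = 100L, acceptor_strand = "+",
                      n_ncl = 6L)
  fus <- data.table(donor_chrom = "chr1", donor_pos = 400L,
                    donor_strand = "+", acceptor_chrom = "chr2",
                    acceptor_pos = 400L, acceptor_strand = "+", n_ncl = 4L)
  harmonized <- list(circTool = harmonize_events(intra, ann),
                     fusTool = harmonize_events(fus, ann),
                     bothTool = harmonize_events(rbind(intra, fus), ann))
  events <- merge_tool_reports(harmonized)
  evidence <- count_junction_reads(events,
                                   data.table(chrom = character(),
                                              intron_start = integer(),
                                              intron_end = integer(),
                                              strand = character(),
                                              unique_read_count = integer()),
                                   ann)
  m <- suppressWarnings(compute_metrics(
    events, evidence,
    tool_scopes = c(circTool = "intragenic", fusTool = "intergenic",
                    bothTool = "both"),
    total_raw_reads = 1e7, total_mapped_reads = 1e7))
  expect_equal(m[locus_class == "intragenic", n_tools], 2L)
  expect_equal(m[locus_class == "intergenic", n_tools], 2L)
})
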