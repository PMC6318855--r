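## build a small merged event set with fabricated calls/evidence/metrics
make_report_inputs <- function(n_intra = 7L, n_inter = 3L,
                               n_ambig = 3L) {
  n <- n_intra + n_inter
  df <- data.table(donor_pos = seq(400L, by = 200L, length.out = n),
                   acceptor_pos = seq(100L, by = 200L, length.out = n),
                   n_ncl = seq_len(n) + 1L)
  df[, locus_class := rep(c("intragenic", "intergenic"),
                          c(n_intra, n_inter))]
  df[, acceptor_genes := fifelse(locus_class == "intergenic", "GB", "GA")]
  ha <- fake_harmonized(df)
  hb <- fake_harmonized(df[seq(1, n, by = 2)])
  events <- merge_tool_reports(list(toolA = ha, toolB = hb))
  status <- rep("ok", n)
  if (n_ambig > 0)
    status[seq_len(n_ambig)] <- rep(c("alt_colinear", "multi_hit"),
                                    length.out = n_ambig)
  calls <- data.table(status = status[match(events$key, ha$key)])
  calls[, key := events$key]
  evidence <- list(
    events = data.table(n_d = 5L, n_a = 6L)[rep(1L, n)][, key := events$key],
    gene_totals = data.table(gene_id = c("GA", "GB"),
                             gene_junction_total = c(100L, 50L)),
    gene_junction_counts = data.table(gene_id = "GA", count = 100L))
  metrics <- data.table(locus_class = events$locus_class,
                        tau_ncl = seq(0, 1, length.out = n),
                        ncl_score = seq(-2, 4, length.out = n),
                        tpm = NA_real_)
  metrics[, key := events$key]
  list(events = events, calls = calls, evidence = evidence,
       metrics = metrics)
}

test_that("assembly splits classes and conserves events across modes", {
  ri <- make_report_inputs()
  res <- assemble_results(ri$events, ri$calls, ri$evidence, ri$metrics,
                          mode = "drop_ambiguous")
  n_main <- nrow(res$intragenic) + nrow(res$intergenic)
  expect_equal(n_main + nrow(res$ambiguous), nrow(ri$events))
  expect_true(all(res$intragenic$status == "ok"))
  expect_true(all(res$intragenic$locus_class == "intragenic"))
  expect_true(all(res$intergenic$locus_class == "intergenic"))

  keep <- assemble_results(ri$events, ri$calls, ri$evidence, ri$metrics,
                           mode = "keep_all")
  expect_equal(nrow(keep$intragenic) + nrow(keep$intergenic),
               nrow(ri$events))
  expect_equal(nrow(keep$ambiguous), 0L)
  expect_true("status" %in% names(keep$intragenic))

  ## per-class accounting identity, the published table's structure
  for (cls in c("intragenic", "intergenic")) {
    before <- nrow(keep[[cls]])
    after <- nrow(res[[cls]])
    n_alt <- sum(res$ambiguous$locus_class == cls &
                   res$ambiguous$status == "alt_colinear")
    n_multi <- sum(res$ambiguous$locus_class == cls &
                     res$ambiguous$status == "multi_hit")
    expect_equal(before, after + n_alt + n_multi)
  }

  ## a metrics row without a matching event is an internal error
  bad <- copy(ri$metrics)[1, key := "chrZ:1:+|chrZ:2:+"]
  expect_error(assemble_results(ri$events, ri$calls, ri$evidence, bad),
               "consistency")
})

test_that("coverage matrix, per-tool summary and histogram are consistent", {
  k1 <- data.table(donor_pos = 400L, acceptor_pos = 100L, n_ncl = 3L)
  k2 <- data.table(donor_pos = 600L, acceptor_pos = 300L, n_ncl = 4L)
  events <- merge_tool_reports(list(
    toolA = fake_harmonized(rbind(k1, k2)),
    toolB = fake_harmonized(k1)))
  cov <- coverage_summary(events)
  expect_equal(cov$per_tool[tool == "toolA", n_detected], 2L)
  expect_equal(cov$per_tool[tool == "toolB", n_detected], 1L)
  expect_equal(cov$per_tool[tool == "toolA", n_specific], 1L)
  expect_equal(cov$histogram$count, c(1, 1))
  expect_equal(sum(cov$histogram$count), nrow(events))
  ## row sums of the membership matrix equal n_supporting_tools
  mm <- as.matrix(cov$matrix[, c("toolA", "toolB")])
  expect_equal(unname(rowSums(mm)),
               as.numeric(events$n_supporting_tools))

  ## per-tool ambiguous fraction: 1 ambiguous of 4 detected -> 0.25
  k34 <- rbind(
    data.table(donor_pos = 800L, acceptor_pos = 500L, n_ncl = 2L),
    data.table(donor_pos = 1000L, acceptor_pos = 700L, n_ncl = 9L))
  ev4 <- merge_tool_reports(list(
    toolA = fake_harmonized(rbind(k1, k2, k34))))
  calls <- data.table(status = c("multi_hit", "ok", "ok", "ok"))
  calls[, key := ev4$key]
  cov4 <- coverage_summary(ev4, calls)
  expect_equal(cov4$per_tool[tool == "toolA", frac_ambiguous], 0.25)
  expect_equal(cov4$per_tool[tool == "toolA", n_multi_hit], 1L)
})

test_that("cumulative distributions enumerate sorted values with step CDFs", {
  rows <- data.table(tau_ncl = c(0, 0.5, 1), ncl_score = c(1, 2, 3),
                     locus_class = "intragenic", status = "ok")
  out <- suppressWarnings(export_distributions(rows))
  cdf <- out[["tau_ncl.intragenic.non_ambiguous"]]
  expect_equal(cdf$value, c(0, 0.5, 1))
  expect_equal(cdf$cdf, c(1, 2, 3) / 3)
  single <- suppressWarnings(export_distributions(
    data.table(tau_ncl = 0.4, ncl_score = 1.2,
               locus_class = "intergenic", status = "ok")))
  expect_equal(single[["tau_ncl.intergenic.non_ambiguous"]]$cdf, 1)
  expect_warning(export_distributions(rows), "empty stratum")
  ## two strata give two tables per metric
  rows2 <- rbind(rows, data.table(tau_ncl = 0.9, ncl_score = -1,
                                  locus_class = "intragenic",
                                  status = "multi_hit"))
  out2 <- suppressWarnings(export_distributions(rows2))
  expect_true(all(c("tau_ncl.intragenic.non_ambiguous",
                    "tau_ncl.intragenic.ambiguous") %in% names(out2)))
})

test_that("report writing is deterministic byte for byte", {
  ri <- make_report_inputs()
  res <- assemble_results(ri$events, ri$calls, ri$evidence, ri$metrics)
  cov <- coverage_summary(ri$events, ri$calls)
  cdfs <- suppressWarnings(export_distributions(
    merge(ri$metrics, ri$calls, by = "key")[
      , .(tau_ncl, ncl_score, locus_class, status)]))
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  write_report_tables(res, cov, cdfs, NULL, d1)
  write_report_tables(res, cov, cdfs, NULL, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  ## missing optional annotations render as NA, never 0
  intra_lines <- readLines(file.path(d1, "intragenic.tsv"))
  header <- strsplit(intra_lines[1], "\t")[[1]]
  first <- strsplit(intra_lines[2], "\t")[[1]]
  expect_equal(first[match("tpm", header)], "NA")
})
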