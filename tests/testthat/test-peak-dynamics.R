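pk <- function(chrom, start, end, strand = "+", gene_id = "g1",
               peak_id = NULL) {
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        strand = strand, gene_id = gene_id)
  if (!is.null(peak_id)) out$peak_id <- peak_id
  out
}

test_that("overlap fractions follow the query-denominated definition", {
  a <- pk("chr1", 100, 200)
  expect_equal(overlap_fraction(a, pk("chr1", 150, 250)), 0.5)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, pk("chr1", 300, 400)), 0)
  expect_equal(overlap_fraction(a, pk("chr2", 100, 200)), 0)
  expect_equal(overlap_fraction(a, pk("chr1", 100, 200, strand = "-")), 0)
  # translation invariance
  shift <- 1234L
  b <- pk("chr1", 150, 250)
  expect_equal(
    overlap_fraction(pk("chr1", 100 + shift, 200 + shift),
                     pk("chr1", 150 + shift, 250 + shift)),
    overlap_fraction(a, b))
  # scaling equivariance
  expect_equal(overlap_fraction(pk("chr1", 200, 400),
                                pk("chr1", 300, 500)), 0.5)
})

test_that("inheritance calls respect the strict >50% rule", {
  cur <- pk("chr1", 100, 200)
  expect_identical(
    classify_inheritance(cur, pk("chr1", 140, 260))$labels$label,
    "inherited")  # 60/100
  expect_identical(
    classify_inheritance(cur, pk("chr1", 151, 260))$labels$label,
    "de_novo")    # 49/100
  expect_identical(
    classify_inheritance(cur, pk("chr1", 150, 260))$labels$label,
    "de_novo")    # exactly 50 is not > 50
  # reciprocal mode additionally requires >50% of the previous peak
  prev_wide <- pk("chr1", 0, 1000)
  expect_identical(
    classify_inheritance(cur, prev_wide)$labels$label, "inherited")
  expect_identical(
    classify_inheritance(cur, prev_wide, reciprocal = TRUE)$labels$label,
    "de_novo")
})

test_that("the TPM filter excludes weakly expressed transcripts", {
  cur <- dplyr::bind_rows(pk("chr1", 100, 200, gene_id = "hi"),
                          pk("chr1", 500, 600, gene_id = "lo"))
  prev <- pk("chr1", 100, 200, gene_id = "hi")
  expr <- tibble::tibble(gene_id = c("hi", "lo"), tpm = c(50, 2))
  res <- classify_inheritance(cur, prev, expression = expr, tpm_min = 5)
  expect_identical(res$labels$gene_id, "hi")
  expect_equal(sum(res$summary$percent), 100)
})

test_that("inheritance agrees with the brute-force oracle on random peaks", {
  set.seed(1)
  cur <- random_peaks(400)
  prev <- random_peaks(400)
  res <- classify_inheritance(cur, prev)
  frac <- oracle_best_overlap(cur, prev)
  expect_equal(res$labels$overlap_frac, frac, tolerance = 1e-12)
  expect_identical(res$labels$label,
                   ifelse(frac > 0.5, "inherited", "de_novo"))
  expect_equal(sum(res$summary$percent), 100)
})

test_that("origin tracing partitions peaks and matches the cascade oracle", {
  set.seed(2)
  stages <- list(hPSC = random_peaks(120), DE = random_peaks(120),
                 PP = random_peaks(120), hILO = random_peaks(120))
  res <- trace_origin(stages)
  ora <- oracle_origin(stages)
  for (st in names(stages)) {
    expect_identical(res$peaks$origin[res$peaks$stage == st], ora[[st]])
  }
  # partition: fractions sum to 1 per stage
  sums <- tapply(res$summary$fraction, res$summary$stage, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
})

test_that("a late peak overlapping several ancestors gets the earliest origin", {
  stages <- list(
    hPSC = pk("chr1", 100, 300, peak_id = "p1"),
    DE = pk("chr1", 120, 320, peak_id = "p2"),
    PP = pk("chr1", 900, 950, peak_id = "p3"),
    hILO = pk("chr1", 110, 310, peak_id = "p4")
  )
  res <- trace_origin(stages)
  expect_identical(res$peaks$origin[res$peaks$peak_id == "p4"], "hPSC")
  expect_identical(res$peaks$origin[res$peaks$peak_id == "p3"], "PP")
  expect_error(trace_origin(stages[1]), "2 stages")
})

test_that("genes bin by peak count into 0-1 / 2-4 / >=5", {
  genes <- sprintf("g%d", 1:5)
  peaks <- tibble::tibble(
    gene_id = c(rep("g1", 3), rep("g2", 5), "g3", rep("gX", 2)),
    stage = "PP")
  expect_warning(res <- bin_genes_by_peak_count(peaks, genes), "unknown")
  got <- res$genes
  expect_identical(as.character(got$bin[got$gene_id == "g1"]), "2-4")
  expect_identical(as.character(got$bin[got$gene_id == "g2"]), ">=5")
  expect_identical(as.character(got$bin[got$gene_id == "g3"]), "0-1")
  expect_identical(as.character(got$bin[got$gene_id == "g4"]), "0-1")
  expect_equal(attr(res, "n_unknown"), 2L)
  sums <- tapply(res$summary$fraction, res$summary$stage, sum)
  expect_equal(as.numeric(sums), 1)
})

test_that("metagene profiles localise peaks and integrate to one", {
  tx <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
                       end = 3000, strand = "+", utr5_len = 1000,
                       cds_len = 1000, utr3_len = 1000, length = 3000)
  # one peak centred mid-CDS
  res <- metagene_distribution(pk("chr1", 1450, 1550), tx,
                               n_bins_per_segment = 10)
  expect_equal(sum(res$count), 1)
  expect_identical(res$segment[which(res$count == 1)], "CDS")
  bw <- 3 / nrow(res)
  expect_equal(sum(res$density) * bw, 1)
  # a peak outside the transcript is skipped and reported
  expect_message(
    res2 <- metagene_distribution(pk("chr1", 90000, 90100), tx),
    "skipped")
  expect_equal(attr(res2, "n_skipped"), 1L)

  # minus-strand midpoints map 5'->3'
  txm <- dplyr::mutate(tx, strand = "-")
  res3 <- metagene_distribution(pk("chr1", 2900, 2960, strand = "-"),
                                txm, n_bins_per_segment = 10)
  expect_identical(res3$segment[which(res3$count == 1)], "5'UTR")
})

test_that("uniform random peaks give a flat metagene profile", {
  tx <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
                       end = 3000, strand = "+", utr5_len = 1000,
                       cds_len = 1000, utr3_len = 1000, length = 3000)
  set.seed(3)
  n <- 3000
  mids <- sample.int(2990, n, replace = TRUE)
  peaks <- tibble::tibble(chrom = "chr1", start = mids, end = mids + 10,
                          strand = "+", gene_id = "g1")
  res <- metagene_distribution(peaks, tx, n_bins_per_segment = 5)
  p0 <- 1 / nrow(res)
  band <- 3 * sqrt(n * p0 * (1 - p0))
  expect_true(all(abs(res$count - n * p0) < band + 3))
})

test_that("DRACH scanning matches exhaustive enumeration", {
  hits <- scan_drach(c(x = "GGACU"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pos, 1L)
  expect_identical(hits$motif, "GGACT")
  expect_equal(nrow(scan_drach(c(x = "CCCCC"))), 0)
  # RNA/DNA equivalence and overlapping matches
  expect_equal(scan_drach(c(a = "ggacu"))$pos, 1L)
  expect_identical(scan_drach(c(a = "GGACAGACT"))$pos, c(1L, 5L))
  # ambiguous characters cannot match but do not break the scan
  expect_equal(nrow(scan_drach(c(a = "GGNCU"))), 0)

  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  expect_identical(scan_drach(c(r = s))$pos, oracle_drach(s))
})
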