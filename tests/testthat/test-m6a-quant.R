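# small deterministic window-count builder: one gene, `n` windows
toy_windows <- function(n = 20, width = 50) {
  tibble::tibble(
    window_id = sprintf("g1:w%04d", seq_len(n)), gene_id = "g1",
    chrom = "chr1", start = (seq_len(n) - 1L) * width,
    end = seq_len(n) * width, strand = "+",
    tx_start = (seq_len(n) - 1L) * width, tx_end = seq_len(n) * width,
    width = width
  )
}

toy_counts <- function(windows, ip, input) {
  dplyr::bind_rows(
    tibble::tibble(window_id = windows$window_id, fraction = "IP",
                   replicate = 1L, count = ip),
    tibble::tibble(window_id = windows$window_id, fraction = "input",
                   replicate = 1L, count = input)
  )
}

test_that("the window caller is silent on null data and fires on enrichment", {
  w <- toy_windows(20)
  null <- call_peaks(toy_counts(w, rep(50, 20), rep(50, 20)), w)
  expect_equal(nrow(null$peaks), 0)

  # spec-style construction: strong single-window enrichment
  ip <- rep(50, 20); input <- rep(50, 20)
  ip[7] <- 300; input[7] <- 20
  res <- call_peaks(toy_counts(w, ip, input), w)
  expect_equal(nrow(res$peaks), 1)
  win7 <- res$windows[res$windows$window_id == w$window_id[7], ]
  # exact conditional-binomial tail oracle
  L_ip <- sum(ip); L_in <- sum(input)
  p_oracle <- pbinom(300 - 1, 300 + 20, L_ip / (L_ip + L_in),
                     lower.tail = FALSE)
  expect_equal(win7$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(win7$p_value, 1e-5)
  expect_gte(win7$ratio, 1.5)
})

test_that("adjacent significant windows merge into one peak", {
  w <- toy_windows(20)
  ip <- rep(50, 20); input <- rep(50, 20)
  ip[8:11] <- 400
  res <- call_peaks(toy_counts(w, ip, input), w)
  expect_equal(nrow(res$peaks), 1)
  expect_equal(res$peaks$n_windows, 4)
  expect_equal(res$peaks$start, w$start[8])
  expect_equal(res$peaks$end, w$end[11])
  # zero-count windows are skipped, zero library errors
  expect_error(call_peaks(toy_counts(w, rep(0, 20), rep(1, 20)), w),
               "zero total")
})

test_that("differential methylation finds constructed hyper peaks only", {
  w <- toy_windows(20)
  base_ip <- rep(200, 20); base_in <- rep(100, 20)
  a <- toy_counts(w, base_ip, base_in)
  same <- differential_peaks(a, a, w)
  expect_true(all(same$tests$label == "ns"))

  ip_b <- base_ip; ip_b[5] <- 200 * 4  # 4-fold gain in one window
  b <- toy_counts(w, ip_b, base_in)
  res <- differential_peaks(a, b, w)
  expect_identical(res$tests$label[res$tests$unit_id == w$window_id[5]],
                   "hyper")
  expect_identical(res$hyper_genes, "g1")
  # antisymmetric: swapping conditions yields hypo
  res_sw <- differential_peaks(b, a, w)
  expect_identical(res_sw$hypo_genes, "g1")
  # peak-level aggregation pools windows
  peaks <- tibble::tibble(peak_id = "p1", gene_id = "g1",
                          start = w$start[5], end = w$end[6])
  res_pk <- differential_peaks(a, b, w, peaks = peaks)
  expect_identical(res_pk$level, "peak")
  expect_equal(nrow(res_pk$tests), 1)
})

test_that("differential methylation controls the null on simulated windows", {
  truth <- simulate_truth(sim_config(n_genes = 150, seed = 6))
  a <- simulate_m6a_counts(truth, stages = "PP", condition = "A")$counts
  b <- simulate_m6a_counts(truth, stages = "PP", condition = "B")$counts
  # same truth, same expectations: everything is null
  w <- tile_windows(truth$transcripts, truth$config$window_size)
  res <- differential_peaks(a, b, w)
  frac <- mean(res$tests$label != "ns")
  n <- nrow(res$tests)
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
})

test_that("relative m6A levels are null-centred and antisymmetric", {
  w <- toy_windows(10)
  cnt <- function(f, r, x) tibble::tibble(
    gene_id = sprintf("g%02d", 1:50), fraction = f, replicate = r,
    count = x)
  set.seed(8)
  base <- rpois(50, 500)
  counts <- dplyr::bind_rows(cnt("IP", 1, base), cnt("IP", 2, base),
                             cnt("input", 1, base), cnt("input", 2, base))
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), tpm = 100)
  res <- relative_m6a_level(counts, expr)
  expect_equal(res$log2fc, rep(0, 50), tolerance = 1e-12)
  expect_false(any(res$m6a_flag))

  # 4x IP on the first 10 genes, high counts
  ip4 <- base; ip4[1:10] <- base[1:10] * 4
  counts2 <- dplyr::bind_rows(cnt("IP", 1, ip4), cnt("IP", 2, ip4),
                              cnt("input", 1, base), cnt("input", 2, base))
  res2 <- relative_m6a_level(counts2, expr)
  expect_true(all(res2$m6a_flag[1:10]))
  expect_false(any(res2$m6a_flag[11:50]))
  # swapping IP and input labels negates the log fold change
  counts_sw <- dplyr::mutate(counts2, fraction = ifelse(
    .data$fraction == "IP", "input", "IP"))
  res_sw <- relative_m6a_level(counts_sw, expr)
  expect_equal(res_sw$log2fc, -res2$log2fc, tolerance = 1e-10)
})

test_that("m6A-expression correlation classifies exact relationships", {
  stages <- c("hPSC", "DE", "PP", "hILO")
  m6a <- tibble::tibble(
    gene_id = rep(c("neg", "flat", "pos"), each = 4),
    stage = rep(stages, 3),
    m6a_level = c(4, 3, 2, 1, 2, 2, 2, 2, 1, 2, 3, 4))
  expr <- tibble::tibble(
    gene_id = rep(c("neg", "flat", "pos"), each = 4),
    stage = rep(stages, 3),
    tpm = c(10, 20, 30, 40, 10, 20, 30, 40, 10, 20, 30, 40))
  res <- correlate_m6a_expression(m6a, expr)
  expect_identical(res$class[res$gene_id == "neg"], "negative")
  expect_identical(res$class[res$gene_id == "pos"], "positive")
  expect_identical(res$class[res$gene_id == "flat"], "none")
  expect_identical(res$flag[res$gene_id == "flat"], "degenerate")
  expect_equal(res$r[res$gene_id == "neg"], -1, tolerance = 1e-12)

  # closed-form covariance oracle on random vectors
  set.seed(9)
  x <- rnorm(4); y <- rnorm(4)
  r_pkg <- correlate_m6a_expression(
    tibble::tibble(gene_id = "g", stage = stages, m6a_level = x),
    tibble::tibble(gene_id = "g", stage = stages, tpm = y))$r
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x)) ^ 2) * sum((y - mean(y)) ^ 2))
  expect_equal(r_pkg, r_oracle, tolerance = 1e-12)
})

test_that("differential expression labels planted drops and keeps the null clean", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:200)
  mk <- function(cond, mu) purrr::map_dfr(1:2, function(r) tibble::tibble(
    gene_id = genes, condition = cond, replicate = r,
    count = rpois(200, mu)))
  base_mu <- rep(800, 200)
  de0 <- differential_expression(dplyr::bind_rows(mk("WT", base_mu),
                                                  mk("KO", base_mu)))
  expect_true(all(de0$label == "ns"))

  drop_mu <- base_mu; drop_mu[1:20] <- 200
  de1 <- differential_expression(dplyr::bind_rows(mk("WT", base_mu),
                                                  mk("KO", drop_mu)))
  expect_true(all(de1$label[1:20] == "down"))
  expect_true(mean(de1$label[21:200] == "ns") > 0.97)
})

test_that("the NB Wald test tracks an established DE implementation", {
  truth <- simulate_truth(sim_config(n_genes = 300, seed = 12))
  planted <- head(truth$transcripts$gene_id, 30)
  wt <- simulate_rnaseq_counts(truth, "WT")
  ko <- simulate_rnaseq_counts(truth, "KO", de_genes = planted,
                               de_fold = 0.25, seed_offset = 1L)
  counts <- dplyr::bind_rows(wt, ko)
  mine <- differential_expression(counts)

  mat <- tidyr::pivot_wider(
    dplyr::mutate(counts, s = paste0(.data$condition, .data$replicate),
                  count = round(.data$count)),
    id_cols = "gene_id", names_from = "s", values_from = "count")
  m <- as.matrix(mat[, -1])
  rownames(m) <- mat$gene_id
  coldata <- data.frame(condition = factor(
    sub("[0-9]+$", "", colnames(m)), levels = c("WT", "KO")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  ref <- ref[mine$gene_id, ]
  cmp <- stats::cor(mine$log2fc, ref$log2FoldChange, use = "complete.obs")
  expect_gt(cmp, 0.95)
  # both routes recover the planted drops
  expect_gt(mean(mine$label[mine$gene_id %in% planted] == "down"), 0.9)
  expect_gt(mean(ref[planted, "padj"] < 0.05, na.rm = TRUE), 0.9)
})

test_that("target screening is an exact, order-safe intersection", {
  s <- screen_targets(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(s$targets, c("B", "C"))
  expect_equal(s$n_targets, 2)
  expect_identical(screen_targets(c("X"), c("Y"))$targets, character(0))
  a <- sprintf("g%d", sample(100, 40))
  b <- sprintf("g%d", sample(100, 40))
  expect_lte(screen_targets(a, b)$n_targets, min(length(unique(a)),
                                                 length(unique(b))))
  expect_identical(screen_targets(a, b)$targets,
                   screen_targets(b, a)$targets)
  expect_identical(tidy(s)$gene_id, c("B", "C"))
  expect_equal(glance(s)$n_targets, 2)
})
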