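test_that("spike-in calibration reproduces exact and degenerate lines", {
  cal <- calibrate_spikeins(c(10, 20, 40), c(1, 2, 4))
  expect_equal(cal$slope, 0.1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$n_spikeins_used, 3L)

  expect_warning(flat <- calibrate_spikeins(c(10, 20, 40), c(2, 2, 2)),
                 "zero variance")
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(calibrate_spikeins(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibrate_spikeins(c(3, 3, 3), c(1, 2, 3)),
               "zero variance")
})

test_that("calibration slope matches the normal-equations oracle", {
  set.seed(11)
  tpm <- sort(runif(12, 1, 200))
  amol <- 0.05 * tpm + 0.3 + rnorm(12, 0, 0.2)
  cal <- calibrate_spikeins(tpm, amol)
  ora <- oracle_ols(tpm, amol)
  expect_equal(cal$slope, ora$slope, tolerance = 1e-10)
  expect_equal(cal$intercept, ora$intercept, tolerance = 1e-10)
  # through-origin variant equals the closed form sum(xy)/sum(x^2)
  cal0 <- calibrate_spikeins(tpm, amol, intercept = FALSE)
  expect_equal(cal0$slope, sum(tpm * amol) / sum(tpm ^ 2),
               tolerance = 1e-12)
  expect_identical(cal0$intercept, 0)
})

test_that("decay fits recover closed-form kinetics", {
  fit <- fit_decay(c(0, 1, 2, 3), c(100, 50, 25, 12.5))
  expect_equal(fit$k_decay, log(2), tolerance = 1e-12)
  expect_equal(fit$t_half, 1, tolerance = 1e-12)
  expect_identical(fit$flag, "ok")

  t <- c(0, 1, 2, 3)
  fit2 <- fit_decay(t, 100 * exp(-0.5 * t))
  expect_equal(fit2$t_half, log(2) / 0.5, tolerance = 1e-12)

  const <- fit_decay(t, rep(7, 4))
  expect_identical(const$flag, "increasing")
  expect_identical(const$t_half, Inf)
  expect_equal(const$k_decay, 0)

  # per-timepoint averaging mode agrees exactly on clean data
  expect_equal(fit_decay(t, 100 * exp(-0.5 * t),
                         mode = "per-timepoint")$k_decay, 0.5,
               tolerance = 1e-12)

  expect_error(fit_decay(c(1, 2, 3), c(3, 2, 1)), "t = 0")
  expect_identical(fit_decay(c(0, 1, 2, 3), c(10, -1, 0, 2))$flag,
                   "insufficient")
})

test_that("noisy decay fits agree with a brute-force grid-search oracle", {
  set.seed(21)
  for (k_true in c(0.2, 0.7, 1.5)) {
    t <- c(0, 1, 2, 3)
    c0 <- 200
    obs <- c0 * exp(-k_true * t) * exp(rnorm(4, 0, 0.1))
    fit <- fit_decay(t, obs)
    k_oracle <- oracle_grid_k(t, obs)
    expect_lt(abs(fit$k_decay - k_oracle), 1e-3)
    expect_lt(abs(fit$k_decay - k_true), 3 * max(fit$slope_se, 1e-6) + 0.3)
  }
})

test_that("the half-life identity and scale invariance hold", {
  set.seed(31)
  for (i in 1:25) {
    t <- c(0, 1, 2, 3)
    obs <- runif(1, 10, 500) * exp(-runif(1, 0.05, 2) * t) *
      exp(rnorm(4, 0, 0.2))
    fit <- fit_decay(t, obs)
    if (fit$flag == "ok") {
      expect_lt(abs(fit$t_half * fit$k_decay - log(2)), 1e-12)
    }
    scaled <- fit_decay(t, obs * 37.5)
    expect_equal(scaled$k_decay, fit$k_decay, tolerance = 1e-12)
  }
})

test_that("half-life tables exactly recover noise-free truths", {
  truth <- .tiny_truth()
  course <- simulate_decay_course(truth, noise = FALSE)
  for (cond in c("WT", "KO")) {
    tab <- estimate_halflives(course[course$condition == cond, ],
                              spikeins = truth$spikeins, tpm_min = 0)
    tr <- truth$halflives[truth$halflives$condition == cond, ]
    err <- abs(tab$t_half - tr$t_half[match(tab$gene_id, tr$gene_id)]) /
      tr$t_half[match(tab$gene_id, tr$gene_id)]
    expect_lt(max(err), 1e-6)
    expect_true(all(tab$flag == "ok"))
  }
})

test_that("calibration cancels when library composition is time-constant", {
  # a compensating species keeps the total molar amount constant, so the
  # TPM rescale is identical at every timepoint and the spike-in
  # calibration reduces to a global constant that cancels in ln(C/C0)
  t <- c(0, 1, 2, 3)
  th <- c(1, 2, 4, 8)
  amounts <- sapply(th, function(h) 100 * 2 ^ (-t / h))
  ballast <- 1000 - rowSums(amounts)
  spikes <- tibble::tibble(spikein_id = sprintf("ERCC-%02d", 1:4),
                           attomoles = c(0.5, 2, 10, 50))
  course <- dplyr::bind_rows(purrr::map(seq_along(t), function(i) {
    tibble::tibble(
      gene_id = c(sprintf("g%d", seq_along(th)), "ballast",
                  spikes$spikein_id),
      condition = "WT", replicate = 1L, timepoint_h = t[i],
      count = c(amounts[i, ], ballast[i], spikes$attomoles) * 1000,
      length = 1000
    )
  }))
  t_spike <- estimate_halflives(course, spikeins = spikes, tpm_min = 0)
  t_none <- estimate_halflives(course, calibration = "none", tpm_min = 0)
  g <- grepl("^g", t_spike$gene_id)
  expect_equal(t_spike$t_half[g], t_none$t_half[g], tolerance = 1e-8)
  expect_equal(sort(t_spike$t_half[g]), th, tolerance = 1e-8)
})

test_that("courses without a zero timepoint or spike-ins are rejected", {
  truth <- .tiny_truth()
  course <- simulate_decay_course(truth, noise = FALSE)
  expect_error(estimate_halflives(course[course$timepoint_h > 0, ],
                                  spikeins = truth$spikeins),
               "t = 0")
  expect_error(estimate_halflives(course[!course$is_spikein, ],
                                  spikeins = truth$spikeins),
               "spike-in")
})

test_that("estimation error shrinks with sequencing depth", {
  med_err <- vapply(c(1e4, 1e5, 1e6), function(d) {
    truth <- simulate_truth(sim_config(n_genes = 150, depth = d,
                                       n_replicates = 3, seed = 5))
    course <- simulate_decay_course(truth, conditions = "WT")
    tab <- estimate_halflives(course, spikeins = truth$spikeins)
    tr <- truth$halflives[truth$halflives$condition == "WT", ]
    ok <- tab$flag == "ok"
    median(abs(tab$t_half[ok] -
                 tr$t_half[match(tab$gene_id[ok], tr$gene_id)]) /
             tr$t_half[match(tab$gene_id[ok], tr$gene_id)])
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("distribution comparison matches exact rank enumeration", {
  tab <- function(ids, t) {
    tibble::tibble(gene_id = ids, condition = "X", C0 = 1, k_decay = 1,
                   k_se = 0, t_half = t, r_squared = 1,
                   n_timepoints_used = 4L, flag = "ok")
  }
  # identical tables: no shift
  a <- tab(sprintf("g%02d", 1:30), seq(1, 10, length.out = 30))
  cmp <- compare_halflife_distributions(a, a)
  expect_equal(cmp$median_a, cmp$median_b)
  expect_gt(cmp$p_value, 0.9)
  # halving every value halves the median
  b <- a
  b$t_half <- a$t_half / 2
  cmp2 <- compare_halflife_distributions(a, b)
  expect_equal(cmp2$median_b, cmp2$median_a / 2)

  # exact enumeration oracle at small n
  set.seed(41)
  for (i in 1:5) {
    x <- round(runif(6, 1, 20), 2)
    y <- round(runif(6, 1, 20), 2)
    ids <- sprintf("s%02d", 1:6)
    cmp3 <- compare_halflife_distributions(tab(ids, x), tab(ids, y),
                                           min_shared = 5)
    ora <- oracle_mann_whitney(x, y)
    expect_equal(unname(cmp3$U_statistic), ora$U)
    expect_equal(cmp3$p_value, ora$p, tolerance = 1e-10)
  }
})

test_that("half-life change classification labels planted effects", {
  tab <- function(k, se, cond) {
    tibble::tibble(gene_id = sprintf("g%03d", seq_along(k)),
                   condition = cond, C0 = 1, k_decay = k, k_se = se,
                   t_half = log(2) / k, r_squared = 1,
                   n_timepoints_used = 4L, flag = "ok")
  }
  k <- rep(0.3, 50)
  a <- tab(k, rep(0.01, 50), "WT")
  expect_true(all(classify_halflife_changes(a, a)$label == "unchanged"))

  # halve the half-life of the first 10 genes, tight standard errors
  kb <- k
  kb[1:10] <- 0.6
  b <- tab(kb, rep(0.01, 50), "KO")
  res <- classify_halflife_changes(a, b)
  expect_true(all(res$label[1:10] == "decreased"))
  expect_true(all(res$label[11:50] == "unchanged"))
  # symmetric: swapping conditions flips the labels
  res_sw <- classify_halflife_changes(b, a)
  expect_true(all(res_sw$label[1:10] == "increased"))

  # invalid fits fall through as unchanged with a flag
  b2 <- b
  b2$flag[1] <- "increasing"
  b2$t_half[1] <- Inf
  res2 <- classify_halflife_changes(a, b2)
  expect_identical(res2$label[1], "unchanged")
  expect_identical(res2$flag[1], "no_valid_fit")
})

test_that("null data do not trigger half-life change calls in excess", {
  truth <- simulate_truth(sim_config(n_genes = 300,
                                     m6a_lifetime_reduction = 0,
                                     n_replicates = 3, seed = 2))
  course <- simulate_decay_course(truth)
  wt <- estimate_halflives(course[course$condition == "WT", ],
                           spikeins = truth$spikeins)
  ko <- estimate_halflives(course[course$condition == "KO", ],
                           spikeins = truth$spikeins)
  res <- classify_halflife_changes(wt, ko)
  frac <- mean(res$label != "unchanged")
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("stratified lifetime changes separate tagged from untagged", {
  truth <- simulate_truth(sim_config(n_genes = 400, n_replicates = 3,
                                     seed = 3))
  course <- simulate_decay_course(truth)
  wt <- estimate_halflives(course[course$condition == "WT", ],
                           spikeins = truth$spikeins)
  ko <- estimate_halflives(course[course$condition == "KO", ],
                           spikeins = truth$spikeins)
  status <- truth$m6a_status[truth$m6a_status$stage == "PP",
                             c("gene_id", "m6a")]
  res <- stratify_lifetime_changes(wt, ko, status)
  m6a_row <- res$strata[res$strata$m6a, ]
  non_row <- res$strata[!res$strata$m6a, ]
  expect_lt(m6a_row$median_ratio, non_row$median_ratio)
  expect_lt(res$p_value, 0.01)
})
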