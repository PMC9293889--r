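# windowed peak calling, differential methylation, relative m6A level,
# m6A-expression correlation, differential expression, target screen

#' Aggregate windowed counts to gene level
#'
#' @param counts long window-count tibble (window_id plus metadata columns).
#' @param windows window tibble mapping window_id to gene_id.
#' @return Long tibble of per-gene counts with the same metadata columns.
#' @export
aggregate_windows_to_genes <- function(counts, windows) {
  assert_columns(counts, c("window_id", "count"), "counts")
  assert_columns(windows, c("window_id", "gene_id"), "windows")
  keys <- intersect(c("stage", "condition", "fraction", "replicate",
                      "sample_id"), names(counts))
  counts %>%
    left_join(windows %>% select("window_id", "gene_id"), by = "window_id") %>%
    group_by(across(all_of(c("gene_id", keys)))) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Call m6A peaks from windowed IP and input counts
#'
#' A simplified window caller: replicates are pooled per fraction and each
#' window is tested with a conditional binomial — given the window's total
#' IP + input count, the IP count is binomial with success probability
#' equal to the IP library's share of the summed library sizes under the
#' null of no enrichment; the one-sided tail p-value asks whether the IP
#' proportion exceeds it. Windows with normalised IP/input ratio at or
#' above `ratio_min` and p below `p_max` are peak windows; adjacent
#' significant windows of a transcript are merged into peaks.
#'
#' @param counts long window counts (window_id, fraction, replicate, count;
#'   optional stage/condition columns are processed per group).
#' @param windows window tibble from [tile_windows()].
#' @param ratio_min minimum normalised IP/input ratio (default 1.5).
#' @param p_max p-value cutoff (default 1e-5).
#' @return A list: `peaks` (merged peaks: chrom, start, end, strand,
#'   gene_id, stage/condition if present, score = normalised ratio over the
#'   merged span, p_value = smallest window p, n_windows) and `windows`
#'   (per-window statistics).
#' @export
call_peaks <- function(counts, windows, ratio_min = 1.5, p_max = 1e-5) {
  assert_columns(counts, c("window_id", "fraction", "count"), "counts")
  if (!all(c("IP", "input") %in% counts$fraction)) {
    abort("`counts` must contain both IP and input fractions")
  }
  group_cols <- intersect(c("stage", "condition"), names(counts))

  win_stats <- counts %>%
    group_by(across(all_of(c(group_cols, "window_id", "fraction")))) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "count",
                       values_fill = 0) %>%
    group_by(across(all_of(group_cols))) %>%
    mutate(ip_libsize = sum(.data$IP), input_libsize = sum(.data$input)) %>%
    ungroup()
  if (any(win_stats$ip_libsize == 0 | win_stats$input_libsize == 0)) {
    abort("a library has zero total counts")
  }
  win_stats <- win_stats %>%
    filter(.data$IP + .data$input > 0) %>%
    mutate(
      ratio = ((.data$IP + 0.5) / .data$ip_libsize) /
        ((.data$input + 0.5) / .data$input_libsize),
      p_null = .data$ip_libsize / (.data$ip_libsize + .data$input_libsize),
      p_value = pbinom(.data$IP - 1, .data$IP + .data$input, .data$p_null,
                       lower.tail = FALSE),
      is_peak = .data$ratio >= ratio_min & .data$p_value < p_max
    ) %>%
    select(-"p_null")

  sig <- win_stats %>%
    filter(.data$is_peak) %>%
    left_join(windows, by = "window_id")
  if (nrow(sig) == 0) {
    return(list(peaks = tibble(), windows = win_stats))
  }
  peaks <- sig %>%
    arrange(across(all_of(c(group_cols, "gene_id", "tx_start")))) %>%
    group_by(across(all_of(c(group_cols, "gene_id")))) %>%
    mutate(run = cumsum(.data$tx_start != dplyr::lag(.data$tx_end,
                                                     default = -1L))) %>%
    group_by(across(all_of(c(group_cols, "gene_id", "run")))) %>%
    summarise(
      chrom = first(.data$chrom), start = min(.data$start),
      end = max(.data$end), strand = first(.data$strand),
      score = ((sum(.data$IP) + 0.5) / first(.data$ip_libsize)) /
        ((sum(.data$input) + 0.5) / first(.data$input_libsize)),
      p_value = min(.data$p_value), n_windows = n(), .groups = "drop"
    ) %>%
    select(-"run") %>%
    mutate(peak_id = sprintf("called%05d", row_number()))
  list(peaks = peaks, windows = win_stats)
}

#' Differential m6A methylation between two conditions
#'
#' For every shared window (optionally restricted to peak windows), the
#' change in IP/input enrichment between conditions is tested with a
#' z-test on the log ratio-of-ratios of pooled, library-size-normalised
#' counts (0.5 pseudocounts), Benjamini-Hochberg adjusted. Windows with
#' `log2` ratio-of-ratios at or above `lfc_min` and adjusted p below
#' `alpha` are hyper-methylated in condition B; hypo symmetrically.
#'
#' When `peaks` are supplied, window counts are first summed within each
#' peak region and the test runs per peak — the resolution at which peak
#' callers of this family test — otherwise every shared window is tested
#' individually.
#'
#' @param counts_a,counts_b long window counts for the two conditions (same
#'   window grid; window_id, fraction, replicate, count).
#' @param windows window tibble (for gene annotation and peak assignment).
#' @param peaks optional peak regions (peak_id, gene_id, start, end);
#'   aggregates windows per peak before testing.
#' @param peak_windows optional character vector of window_ids to test
#'   (e.g. windows inside called peaks); `NULL` tests all shared windows.
#'   Ignored when `peaks` is given.
#' @param lfc_min minimum |log2 ratio-of-ratios| (default 1).
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @return A list: `tests` (per-unit statistics and label in
#'   hyper/hypo/ns), `level` (`"peak"` or `"window"`), `hyper_genes`,
#'   `hypo_genes` (genes with any hyper/hypo unit).
#' @export
differential_peaks <- function(counts_a, counts_b, windows, peaks = NULL,
                               peak_windows = NULL, lfc_min = 1,
                               alpha = 0.05) {
  pool <- function(counts, suffix) {
    assert_columns(counts, c("window_id", "fraction", "count"), "counts")
    counts %>%
      group_by(.data$window_id, .data$fraction) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "fraction", values_from = "count",
                         values_fill = 0) %>%
      mutate(L_ip = sum(.data$IP), L_in = sum(.data$input)) %>%
      rename_with(~ paste0(.x, suffix), c("IP", "input", "L_ip", "L_in"))
  }
  df <- inner_join(pool(counts_a, "_a"), pool(counts_b, "_b"),
                   by = "window_id")
  if (nrow(df) == 0) abort("conditions share no windows")
  if (!is.null(peaks)) {
    assert_columns(peaks, c("peak_id", "gene_id", "start", "end"), "peaks")
    membership <- windows %>%
      select("window_id", "gene_id", w_start = "start", w_end = "end") %>%
      inner_join(peaks %>% select("peak_id", "gene_id",
                                  p_start = "start", p_end = "end"),
                 by = "gene_id", relationship = "many-to-many") %>%
      filter(.data$w_start < .data$p_end, .data$p_start < .data$w_end) %>%
      distinct(.data$window_id, .keep_all = TRUE) %>%
      select("window_id", "peak_id")
    df <- df %>%
      inner_join(membership, by = "window_id") %>%
      group_by(.data$peak_id) %>%
      summarise(across(c("IP_a", "input_a", "IP_b", "input_b"), sum),
                across(c("L_ip_a", "L_in_a", "L_ip_b", "L_in_b"), first),
                .groups = "drop") %>%
      rename(unit_id = "peak_id")
    unit_gene <- peaks %>% select(unit_id = "peak_id", "gene_id")
  } else {
    if (!is.null(peak_windows)) {
      df <- df %>% filter(.data$window_id %in% peak_windows)
    }
    df <- df %>% rename(unit_id = "window_id")
    unit_gene <- windows %>% select(unit_id = "window_id", "gene_id")
  }
  df <- df %>%
    mutate(
      lor = log2(((.data$IP_b + 0.5) / .data$L_ip_b) /
                   ((.data$input_b + 0.5) / .data$L_in_b)) -
        log2(((.data$IP_a + 0.5) / .data$L_ip_a) /
               ((.data$input_a + 0.5) / .data$L_in_a)),
      se = sqrt(1 / (.data$IP_a + 0.5) + 1 / (.data$input_a + 0.5) +
                  1 / (.data$IP_b + 0.5) + 1 / (.data$input_b + 0.5)) /
        log(2),
      z = .data$lor / .data$se,
      p_value = 2 * pnorm(-abs(.data$z)),
      padj = p.adjust(.data$p_value, method = "BH"),
      label = case_when(
        .data$lor >= lfc_min & .data$padj < alpha ~ "hyper",
        .data$lor <= -lfc_min & .data$padj < alpha ~ "hypo",
        TRUE ~ "ns"
      )
    ) %>%
    left_join(unit_gene, by = "unit_id")
  list(
    tests = df,
    level = if (is.null(peaks)) "window" else "peak",
    hyper_genes = df %>% filter(.data$label == "hyper") %>%
      pull("gene_id") %>% unique() %>% sort(),
    hypo_genes = df %>% filter(.data$label == "hypo") %>%
      pull("gene_id") %>% unique() %>% sort()
  )
}

# Negative-binomial Wald test between two groups of count libraries.
# Median-of-ratios size factors; per-gene method-of-moments dispersion with
# a floor of 0.01 and no shrinkage (plumbing-grade, deliberately simpler
# than a full GLM machinery).
nb_wald <- function(counts, group_col, group_a, group_b,
                    dispersion_floor = 0.01) {
  assert_columns(counts, c("gene_id", group_col, "count"), "counts")
  counts <- counts %>%
    filter(.data[[group_col]] %in% c(group_a, group_b)) %>%
    mutate(.grp = ifelse(.data[[group_col]] == group_a, "A", "B"))
  sample_cols <- intersect(c("replicate", "sample_id"), names(counts))
  if (length(sample_cols) == 0) {
    abort("`counts` needs a replicate or sample_id column")
  }
  counts$.sample <- paste(counts$.grp,
                          do.call(paste, c(counts[sample_cols], sep = "_")),
                          sep = ".")
  mat <- counts %>%
    select("gene_id", ".sample", "count") %>%
    tidyr::pivot_wider(names_from = ".sample", values_from = "count",
                       values_fill = 0)
  genes <- mat$gene_id
  m <- as.matrix(mat[, -1, drop = FALSE])
  grp <- ifelse(startsWith(colnames(m), "A."), "A", "B")
  if (sum(grp == "A") < 2 || sum(grp == "B") < 2) {
    abort("need at least 2 replicates per condition")
  }

  # median-of-ratios size factors over genes expressed everywhere;
  # fall back to total-count factors when (almost) no gene qualifies
  pos <- rowSums(m > 0) == ncol(m)
  if (sum(pos) >= 5) {
    logg <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - logg)))
  } else {
    tot <- colSums(m)
    if (any(tot == 0)) abort("a library has zero total counts")
    sf <- tot / exp(mean(log(tot)))
  }
  q <- sweep(m, 2, sf, "/")

  qa <- q[, grp == "A", drop = FALSE]
  qb <- q[, grp == "B", drop = FALSE]
  mu_a <- rowMeans(qa)
  mu_b <- rowMeans(qb)
  na <- ncol(qa)
  nb <- ncol(qb)
  # pooled within-group variance -> MoM dispersion, floored
  ss <- rowSums((qa - mu_a) ^ 2) + rowSums((qb - mu_b) ^ 2)
  s2 <- ss / (na + nb - 2)
  mu_all <- (na * mu_a + nb * mu_b) / (na + nb)
  alpha_hat <- pmax(dispersion_floor,
                    (s2 - mu_all) / pmax(mu_all, 1e-8) ^ 2)

  log2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  v_a <- (1 / (mu_a + 0.5) + alpha_hat) / na
  v_b <- (1 / (mu_b + 0.5) + alpha_hat) / nb
  se <- sqrt(v_a + v_b) / log(2)
  z <- log2fc / se
  all_zero <- mu_a + mu_b == 0
  p <- ifelse(all_zero, NA_real_, 2 * pnorm(-abs(z)))
  padj <- rep(NA_real_, length(p))
  padj[!all_zero] <- p.adjust(p[!all_zero], method = "BH")
  tibble(
    gene_id = genes, base_mean = mu_all, mean_a = mu_a, mean_b = mu_b,
    dispersion = alpha_hat, log2fc = ifelse(all_zero, NA_real_, log2fc),
    se = se, z = ifelse(all_zero, NA_real_, z), p_value = p, padj = padj,
    flag = ifelse(all_zero, "all_zero", "ok")
  )
}

#' Differential gene expression between two conditions
#'
#' Plumbing-grade negative-binomial Wald test: median-of-ratios size
#' factors, per-gene method-of-moments dispersion floored at 0.01, no
#' empirical-Bayes shrinkage, Benjamini-Hochberg adjustment. Genes are
#' labelled `up` when the fold change (condition B over A) exceeds 1.5 with
#' adjusted p below `alpha`, `down` when it is below 0.67, `ns` otherwise.
#'
#' @param counts long tibble of gene-level counts: gene_id, a condition
#'   column, replicate (or sample_id), count.
#' @param condition_a,condition_b reference and contrast labels.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param fc_up,fc_down linear fold-change cutoffs (defaults 1.5 and 0.67).
#' @param condition_col name of the condition column.
#' @return Tibble with per-gene log2fc, p_value, padj and label.
#' @export
differential_expression <- function(counts, condition_a = "WT",
                                    condition_b = "KO", alpha = 0.05,
                                    fc_up = 1.5, fc_down = 0.67,
                                    condition_col = "condition") {
  res <- nb_wald(counts, condition_col, condition_a, condition_b)
  res %>%
    mutate(label = case_when(
      .data$flag != "ok" ~ "ns",
      .data$log2fc > log2(fc_up) & .data$padj < alpha ~ "up",
      .data$log2fc < log2(fc_down) & .data$padj < alpha ~ "down",
      TRUE ~ "ns"
    ))
}

#' Relative m6A level per gene from IP and input counts
#'
#' The moderately normalised IP-over-input log2 fold change from the
#' negative-binomial Wald test is taken as the gene's relative m6A level.
#' High-confidence m6A-tagged genes require input TPM above 5, fold change
#' above 1.5 and adjusted p below 0.05 (all thresholds adjustable).
#'
#' @param counts long gene-level counts with a `fraction` column holding
#'   `IP` and `input`, plus replicate (or sample_id); an optional `stage`
#'   column is processed per stage.
#' @param expression tibble (gene_id, tpm; optional stage) of input-sample
#'   expression used for the TPM filter.
#' @param tpm_min,fc_min,alpha flag thresholds.
#' @return Tibble: gene_id (stage), log2fc, p_value, padj, tpm, m6a_flag.
#' @export
relative_m6a_level <- function(counts, expression, tpm_min = 5,
                               fc_min = 1.5, alpha = 0.05) {
  assert_columns(counts, c("gene_id", "fraction", "count"), "counts")
  assert_columns(expression, c("gene_id", "tpm"), "expression")
  by_stage <- "stage" %in% names(counts)
  run_one <- function(cnt, expr) {
    nb_wald(cnt, "fraction", "input", "IP") %>%
      left_join(expr %>% select("gene_id", "tpm"), by = "gene_id") %>%
      mutate(m6a_flag = !is.na(.data$tpm) & .data$tpm > tpm_min &
               .data$flag == "ok" &
               .data$log2fc > log2(fc_min) & .data$padj < alpha) %>%
      select("gene_id", "log2fc", "p_value", "padj", "tpm", "m6a_flag")
  }
  if (by_stage) {
    purrr::map_dfr(unique(counts$stage), function(st) {
      expr <- if ("stage" %in% names(expression)) {
        expression %>% filter(.data$stage == st)
      } else expression
      run_one(counts %>% filter(.data$stage == st), expr) %>%
        mutate(stage = st, .after = "gene_id")
    })
  } else {
    run_one(counts, expression)
  }
}

#' Correlate per-gene m6A level with expression across stages
#'
#' Pearson correlation between a gene's relative m6A level and its
#' expression over the differentiation stages, with a two-sided test.
#' Genes with |r| above `r_min` and p below `alpha` are classed `positive`
#' or `negative` by the sign of r; all others (including degenerate
#' zero-variance genes) are `none`.
#'
#' @param m6a_levels tibble: gene_id, stage, m6a_level.
#' @param expression tibble: gene_id, stage, tpm.
#' @param r_min,alpha classification thresholds (defaults 0.5 and 0.05).
#' @param min_stages minimum paired observations per gene.
#' @return Tibble: gene_id, n, r, p_value, class, flag.
#' @export
correlate_m6a_expression <- function(m6a_levels, expression, r_min = 0.5,
                                     alpha = 0.05, min_stages = 3) {
  assert_columns(m6a_levels, c("gene_id", "stage", "m6a_level"),
                 "m6a_levels")
  assert_columns(expression, c("gene_id", "stage", "tpm"), "expression")
  df <- inner_join(m6a_levels, expression, by = c("gene_id", "stage"))
  df %>%
    group_by(.data$gene_id) %>%
    summarise(
      n = sum(complete.cases(.data$m6a_level, .data$tpm)),
      degenerate = n < min_stages ||
        var(.data$m6a_level, na.rm = TRUE) == 0 ||
        var(.data$tpm, na.rm = TRUE) == 0,
      r = if (degenerate) NA_real_ else
        cor(.data$m6a_level, .data$tpm, use = "complete.obs"),
      p_value = if (degenerate) NA_real_ else
        cor.test(.data$m6a_level, .data$tpm)$p.value,
      .groups = "drop"
    ) %>%
    mutate(
      class = case_when(
        is.na(.data$r) ~ "none",
        abs(.data$r) > r_min & .data$p_value < alpha & .data$r > 0 ~
          "positive",
        abs(.data$r) > r_min & .data$p_value < alpha ~ "negative",
        TRUE ~ "none"
      ),
      flag = ifelse(.data$degenerate, "degenerate", "ok")
    ) %>%
    select(-"degenerate")
}

#' Screen for hyper-methylated and downregulated target genes
#'
#' The integrative target screen: candidate targets of an m6A demethylase
#' are the genes that gain methylation upon its loss AND drop in
#' expression — the exact intersection of the two input sets.
#'
#' @param hyper_genes gene ids with significantly higher m6A in the
#'   perturbed condition.
#' @param down_genes significantly downregulated gene ids.
#' @return An object of class `target_screen`: `targets` (sorted
#'   intersection), `n_hyper`, `n_down`, `n_targets`.
#' @examples
#' screen_targets(c("A", "B", "C"), c("B", "C", "D"))
#' @export
screen_targets <- function(hyper_genes, down_genes) {
  hyper <- unique(as.character(hyper_genes))
  down <- unique(as.character(down_genes))
  structure(
    list(targets = sort(intersect(hyper, down)),
         n_hyper = length(hyper), n_down = length(down),
         n_targets = length(intersect(hyper, down))),
    class = "target_screen"
  )
}

#' @export
print.target_screen <- function(x, ...) {
  cat(sprintf(
    "<target_screen> %d hyper-m6A genes, %d downregulated, %d candidate targets\n",
    x$n_hyper, x$n_down, x$n_targets))
  if (x$n_targets > 0) {
    cat("  ", paste(head(x$targets, 10), collapse = ", "),
        if (x$n_targets > 10) "..." else "", "\n")
  }
  invisible(x)
}
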