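#' Calibrate relative abundance against ERCC spike-ins
#'
#' Ordinary least-squares fit of known spike-in amounts (attomoles) on
#' measured relative abundance (TPM), the standard route from within-sample
#' relative units to absolute molar amounts.
#'
#' @param tpm measured spike-in TPM values.
#' @param attomoles known spike-in amounts.
#' @param intercept fit a free intercept (default) or force the line
#'   through the origin (`FALSE`). Zero TPM implies zero molecules, so the
#'   through-origin fit is the safer conversion for low-abundance
#'   transcripts: an intercept wobble of a fraction of an attomole —
#'   inevitable when standards span three decades — dwarfs their signal.
#' @return An object of class `spikein_calibration` with fields `slope`
#'   (attomoles per TPM), `intercept` (attomoles), `r_squared` and
#'   `n_spikeins_used`.
#' @examples
#' cal <- calibrate_spikeins(c(10, 20, 40), c(1, 2, 4))
#' cal$slope
#' @export
calibrate_spikeins <- function(tpm, attomoles, intercept = TRUE) {
  if (length(tpm) != length(attomoles)) {
    abort("`tpm` and `attomoles` must have equal length")
  }
  use <- is.finite(tpm) & is.finite(attomoles) & tpm > 0
  if (sum(use) < 3) {
    abort("need at least 3 spike-ins with positive TPM to calibrate")
  }
  x <- tpm[use]
  y <- attomoles[use]
  if (var(x) == 0) {
    abort("spike-in TPM values have zero variance; calibration is degenerate")
  }
  if (intercept) {
    fit <- lm(y ~ x)
    b <- unname(coef(fit)[1])
    a <- unname(coef(fit)[2])
    resid <- fit$residuals
  } else {
    a <- sum(x * y) / sum(x ^ 2)
    b <- 0
    resid <- y - a * x
  }
  ss_res <- sum(resid ^ 2)
  ss_tot <- sum((y - mean(y)) ^ 2)
  r2 <- if (ss_tot == 0) {
    warn("spike-in amounts have zero variance; slope is 0")
    1
  } else 1 - ss_res / ss_tot
  structure(
    list(slope = a, intercept = b, r_squared = r2,
         n_spikeins_used = sum(use)),
    class = "spikein_calibration"
  )
}

#' @export
print.spikein_calibration <- function(x, ...) {
  cat(sprintf(
    "<spikein_calibration> slope %.4g amol/TPM, intercept %.4g amol, R^2 %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_spikeins_used))
  invisible(x)
}

# closed-form OLS of y on x returning slope, intercept, slope SE and R^2;
# shared by fit_decay() and the vectorised table path so both agree exactly
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx) ^ 2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  s2 <- if (n > 2) sum(resid ^ 2) / (n - 2) else 0
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       r_squared = if (sum((y - my) ^ 2) == 0) 1
       else 1 - sum(resid ^ 2) / sum((y - my) ^ 2))
}

#' Fit first-order decay to one transcript's time course
#'
#' After transcription shutoff, concentration follows `dC/dt = -k C`, so
#' `ln(C/C0) = -k t` and the half-life is `t1/2 = ln(2) / k`. The decay rate
#' is the negated slope of a least-squares regression of `ln(C/C0)` on time
#' across all timepoints (intercept left free to absorb t = 0 sampling
#' noise). Non-positive abundances are dropped; fewer than 3 surviving
#' timepoints flags the fit as insufficient, and a non-positive rate flags
#' it as increasing (half-life undefined).
#'
#' @param times sampling times, hours.
#' @param abundances abundances on any positive scale (calibrated attomoles
#'   in the full pipeline); the scale cancels in `ln(C/C0)`.
#' @param mode `"regression"` (default, single fit across timepoints) or
#'   `"per-timepoint"`: mean of the per-timepoint rates
#'   `ln(C0/Ct) / t` over the non-zero times, a literal per-timepoint
#'   averaging of the same model.
#' @return An object of class `decay_fit`: `C0`, `k_decay` (per hour),
#'   `t_half` (hours; `Inf` when not decaying), `slope_se`,
#'   `n_timepoints_used`, `r_squared`, `flag` in
#'   `c("ok", "increasing", "insufficient")`.
#' @examples
#' fit_decay(c(0, 1, 2, 3), c(100, 50, 25, 12.5))$t_half  # exactly 1 h
#' @export
fit_decay <- function(times, abundances, mode = c("regression",
                                                  "per-timepoint")) {
  mode <- match.arg(mode)
  if (length(times) != length(abundances)) {
    abort("`times` and `abundances` must have equal length")
  }
  if (!0 %in% times) abort("a t = 0 measurement is required (C0 undefined)")
  keep <- is.finite(abundances) & abundances > 0 & is.finite(times)
  times <- times[keep]
  abundances <- abundances[keep]
  C0 <- abundances[match(0, times)]
  out <- list(C0 = if (length(C0)) C0 else NA_real_, k_decay = NA_real_,
              t_half = NA_real_, slope_se = NA_real_,
              n_timepoints_used = length(times), r_squared = NA_real_,
              flag = "insufficient")
  class(out) <- "decay_fit"
  if (length(times) < 3 || is.na(out$C0)) return(out)

  y <- log(abundances / out$C0)
  if (mode == "regression") {
    fit <- ols_line(times, y)
    k <- -fit$slope
    out$slope_se <- fit$slope_se
    out$r_squared <- fit$r_squared
  } else {
    tt <- times[times > 0]
    ks <- -y[times > 0] / tt
    k <- mean(ks)
    out$slope_se <- if (length(ks) > 1) sd(ks) / sqrt(length(ks)) else 0
    out$r_squared <- NA_real_
  }
  out$n_timepoints_used <- length(times)
  if (!is.finite(k) || k <= 0) {
    out$k_decay <- max(k, 0)
    out$t_half <- Inf
    out$flag <- "increasing"
  } else {
    out$k_decay <- k
    out$t_half <- log(2) / k
    out$flag <- "ok"
  }
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.4g /h, t1/2 = %.4g h, se(k) = %.3g, n = %d, flag = %s\n",
    x$k_decay, x$t_half, x$slope_se, x$n_timepoints_used, x$flag))
  invisible(x)
}

#' Estimate half-lives for every transcript in a decay course
#'
#' The full stability-profiling pipeline: counts are TPM-normalised within
#' each library, converted to absolute attomoles by per-timepoint linear
#' spike-in calibration, averaged across replicates, and each transcript's
#' decay rate and half-life are fitted across the 0/1/2/3 h timepoints with
#' [fit_decay()].
#'
#' @param course long decay-course tibble with columns gene_id, condition,
#'   replicate, timepoint_h, count, length; spike-in rows are identified by
#'   an `ERCC-` id prefix (or an `is_spikein` column).
#' @param spikeins tibble of spike-in truth (spikein_id, attomoles);
#'   required when `calibration = "spikein"`.
#' @param calibration `"spikein"` (absolute calibration; default) or
#'   `"none"` (fit on TPM directly).
#' @param calibration_intercept fit the conversion with a free intercept;
#'   default `FALSE` (through the origin), see [calibrate_spikeins()].
#' @param mode fitting mode passed to [fit_decay()].
#' @param tpm_min transcripts with t = 0 TPM at or below this are flagged
#'   `insufficient` and excluded from downstream medians (low-expression
#'   filter). Default 5.
#' @return A `halflife_table` tibble: gene_id, condition, C0, k_decay, k_se,
#'   t_half, r_squared, n_timepoints_used, flag.
#' @export
estimate_halflives <- function(course, spikeins = NULL,
                               calibration = c("spikein", "none"),
                               mode = c("regression", "per-timepoint"),
                               tpm_min = 5,
                               calibration_intercept = FALSE) {
  calibration <- match.arg(calibration)
  mode <- match.arg(mode)
  assert_columns(course, c("gene_id", "condition", "replicate",
                           "timepoint_h", "count", "length"), "course")
  if (!0 %in% course$timepoint_h) {
    abort("decay course lacks the t = 0 timepoint; C0 is undefined")
  }
  if (!"is_spikein" %in% names(course)) {
    course <- course %>% mutate(is_spikein = grepl("^ERCC-", .data$gene_id))
  }
  if (calibration == "spikein") {
    if (is.null(spikeins)) {
      abort("`spikeins` truth is required for spike-in calibration")
    }
    assert_columns(spikeins, c("spikein_id", "attomoles"), "spikeins")
    if (!any(course$is_spikein)) {
      abort("no spike-in rows found in the course")
    }
  }

  # zero counts get a 0.5 pseudocount so the timepoint survives the log
  # transform instead of being dropped (slight bias for a retained point)
  course <- course %>%
    mutate(count = ifelse(.data$count == 0, 0.5, .data$count))

  # TPM within each library, then calibrate each library to attomoles
  course <- course %>%
    group_by(.data$condition, .data$replicate, .data$timepoint_h) %>%
    mutate(tpm = tpm_from_counts(.data$count, .data$length)) %>%
    ungroup()

  if (calibration == "spikein") {
    course <- course %>%
      group_by(.data$condition, .data$replicate, .data$timepoint_h) %>%
      dplyr::group_modify(function(df, key) {
        sp <- df %>%
          filter(.data$is_spikein) %>%
          left_join(spikeins, by = c(gene_id = "spikein_id"))
        cal <- calibrate_spikeins(sp$tpm, sp$attomoles,
                                  intercept = calibration_intercept)
        df %>% mutate(abundance = cal$intercept + cal$slope * .data$tpm)
      }) %>%
      ungroup()
  } else {
    course <- course %>% mutate(abundance = .data$tpm)
  }

  # replicate-mean abundance per timepoint, then one fit per transcript
  per_gene <- course %>%
    filter(!.data$is_spikein) %>%
    group_by(.data$gene_id, .data$condition, .data$timepoint_h) %>%
    summarise(abundance = mean(.data$abundance), tpm = mean(.data$tpm),
              .groups = "drop")

  low_expr <- per_gene %>%
    filter(.data$timepoint_h == 0, .data$tpm <= tpm_min) %>%
    mutate(key = paste(.data$gene_id, .data$condition)) %>%
    pull("key")

  out <- per_gene %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(fit = list(fit_decay(.data$timepoint_h, .data$abundance,
                                   mode = mode)),
              .groups = "drop") %>%
    mutate(
      C0 = purrr::map_dbl(.data$fit, "C0"),
      k_decay = purrr::map_dbl(.data$fit, "k_decay"),
      k_se = purrr::map_dbl(.data$fit, "slope_se"),
      t_half = purrr::map_dbl(.data$fit, "t_half"),
      r_squared = purrr::map_dbl(.data$fit, "r_squared"),
      n_timepoints_used = purrr::map_int(.data$fit,
                                         ~ as.integer(.x$n_timepoints_used)),
      flag = purrr::map_chr(.data$fit, "flag")
    ) %>%
    select(-"fit") %>%
    mutate(flag = ifelse(paste(.data$gene_id, .data$condition) %in% low_expr,
                         "insufficient", .data$flag))
  class(out) <- c("halflife_table", class(out))
  out
}

#' Compare two half-life distributions
#'
#' Two-sided Mann-Whitney U test on the half-lives of transcripts with a
#' valid (`flag == "ok"`) fit in both tables, with medians per condition.
#'
#' @param table_a,table_b `halflife_table`s (e.g. WT and KO).
#' @param min_shared minimum number of shared valid transcripts.
#' @return An object of class `halflife_comparison`: medians, U statistic,
#'   p-value, group sizes and the underlying paired tibble.
#' @export
compare_halflife_distributions <- function(table_a, table_b,
                                           min_shared = 20) {
  a <- table_a %>% filter(.data$flag == "ok")
  b <- table_b %>% filter(.data$flag == "ok")
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < min_shared) {
    abort(sprintf("only %d shared valid transcripts (need >= %d)",
                  length(shared), min_shared))
  }
  ta <- a$t_half[match(shared, a$gene_id)]
  tb <- b$t_half[match(shared, b$gene_id)]
  wt <- suppressWarnings(wilcox.test(ta, tb, alternative = "two.sided"))
  structure(
    list(median_a = median(ta), median_b = median(tb),
         U_statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(ta), n_b = length(tb),
         label_a = unique(table_a$condition)[1] %||% "A",
         label_b = unique(table_b$condition)[1] %||% "B",
         data = tibble(gene_id = shared, t_half_a = ta, t_half_b = tb)),
    class = "halflife_comparison"
  )
}

#' @export
print.halflife_comparison <- function(x, ...) {
  cat("<halflife_comparison>\n")
  cat(sprintf("  median %s: %.3g h (n = %d)\n", x$label_a, x$median_a, x$n_a))
  cat(sprintf("  median %s: %.3g h (n = %d)\n", x$label_b, x$median_b, x$n_b))
  cat(sprintf("  Mann-Whitney U = %.4g, p = %.3g\n", x$U_statistic,
              x$p_value))
  invisible(x)
}

#' Stratified lifetime change between conditions by m6A status
#'
#' For each transcript shared between two half-life tables, computes the
#' lifetime ratio (condition B over A) and its log2, then contrasts the
#' m6A-tagged and untagged strata with a two-sided Mann-Whitney U test —
#' the comparison behind cumulative-distribution plots of lifetime change
#' for methylated versus unmethylated transcripts.
#'
#' @param table_a,table_b `halflife_table`s (reference and perturbed).
#' @param m6a_status tibble with columns gene_id and logical m6a.
#' @return A list: `strata` tibble (per-stratum n, mean/median ratio,
#'   median log2 fold change), `p_value` of the between-stratum test, and
#'   the per-gene `data`.
#' @export
stratify_lifetime_changes <- function(table_a, table_b, m6a_status) {
  assert_columns(m6a_status, c("gene_id", "m6a"), "m6a_status")
  a <- table_a %>% filter(.data$flag == "ok")
  b <- table_b %>% filter(.data$flag == "ok")
  shared <- intersect(a$gene_id, b$gene_id)
  df <- tibble(
    gene_id = shared,
    ratio = b$t_half[match(shared, b$gene_id)] /
      a$t_half[match(shared, a$gene_id)]
  ) %>%
    mutate(log2fc = log2(.data$ratio)) %>%
    inner_join(m6a_status %>% distinct(.data$gene_id, .data$m6a),
               by = "gene_id")
  strata <- df %>%
    group_by(.data$m6a) %>%
    summarise(n = n(), mean_ratio = mean(.data$ratio),
              median_ratio = median(.data$ratio),
              median_log2fc = median(.data$log2fc), .groups = "drop")
  if (n_distinct(df$m6a) < 2) {
    warn("one m6A stratum is empty; between-stratum test skipped")
    p <- NA_real_
  } else {
    p <- suppressWarnings(
      wilcox.test(log2fc ~ m6a, data = df, alternative = "two.sided")$p.value
    )
  }
  list(strata = strata, p_value = p, data = df)
}

#' Classify per-transcript half-life changes between conditions
#'
#' A Wald z-test on the difference of fitted decay-rate slopes
#' (`k_B - k_A`) using their regression standard errors, Benjamini-Hochberg
#' adjusted across transcripts. A transcript is labelled `decreased` when
#' its half-life ratio (B/A) falls below `1/fc_threshold` with adjusted
#' p below `alpha`; `increased` symmetrically; otherwise `unchanged`.
#' Transcripts without a valid fit on either side are `unchanged` with a
#' flag.
#'
#' @param table_a,table_b `halflife_table`s (reference and perturbed).
#' @param alpha adjusted-p significance cutoff.
#' @param fc_threshold fold-change cutoff on the half-life ratio.
#' @return Tibble: gene_id, t_half_a, t_half_b, ratio, z, p_value, padj,
#'   label, flag.
#' @export
classify_halflife_changes <- function(table_a, table_b, alpha = 0.05,
                                      fc_threshold = 1.5) {
  if (fc_threshold <= 1) abort("`fc_threshold` must exceed 1")
  df <- inner_join(
    table_a %>% select("gene_id", k_a = "k_decay", se_a = "k_se",
                       t_half_a = "t_half", flag_a = "flag"),
    table_b %>% select("gene_id", k_b = "k_decay", se_b = "k_se",
                       t_half_b = "t_half", flag_b = "flag"),
    by = "gene_id"
  ) %>%
    mutate(
      valid = .data$flag_a == "ok" & .data$flag_b == "ok",
      se = sqrt(.data$se_a ^ 2 + .data$se_b ^ 2),
      z = ifelse(.data$valid,
                 ifelse(.data$se > 0, (.data$k_b - .data$k_a) / .data$se,
                        ifelse(.data$k_b == .data$k_a, 0, Inf *
                                 sign(.data$k_b - .data$k_a))),
                 NA_real_),
      p_value = ifelse(.data$valid, 2 * pnorm(-abs(.data$z)), NA_real_),
      ratio = .data$t_half_b / .data$t_half_a
    )
  df$padj <- NA_real_
  df$padj[df$valid] <- p.adjust(df$p_value[df$valid], method = "BH")
  df %>%
    mutate(
      label = case_when(
        !.data$valid ~ "unchanged",
        .data$padj < alpha & .data$ratio < 1 / fc_threshold ~ "decreased",
        .data$padj < alpha & .data$ratio > fc_threshold ~ "increased",
        TRUE ~ "unchanged"
      ),
      flag = ifelse(.data$valid, "ok", "no_valid_fit")
    ) %>%
    select("gene_id", "t_half_a", "t_half_b", "ratio", "z", "p_value",
           "padj", "label", "flag")
}
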