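#' m6A-RIP-qPCR enrichment, reference-gene normalised
#'
#' For each target gene, expression in IP and input is first normalised to
#' a reference gene (GAPDH-like), and enrichment is the normalised IP over
#' input: `2^-[(Ct_tgt,IP - Ct_ref,IP) - (Ct_tgt,input - Ct_ref,input)]`.
#' Replicates are paired by index; per-replicate enrichments are
#' aggregated by geometric mean (arithmetic on the ddCt scale) with its sd.
#'
#' @param ct tibble with columns gene_id, fraction (`IP`/`input`),
#'   replicate, ct; cycles must be positive.
#' @param reference reference gene id; defaults to the table's `reference`
#'   attribute, else `"GAPDH"`.
#' @return Tibble: gene_id, n_replicates, enrichment (geometric mean),
#'   log2_sd, enrichment per replicate in a list column.
#' @export
m6a_rip_enrichment <- function(ct, reference = NULL) {
  assert_columns(ct, c("gene_id", "fraction", "replicate", "ct"), "ct")
  reference <- reference %||% attr(ct, "reference") %||% "GAPDH"
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) {
    abort("all Ct values must be finite and positive")
  }
  wide <- ct %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "ct")
  for (fr in c("IP", "input")) {
    if (!fr %in% names(wide) || anyNA(wide[[fr]])) {
      bad <- if (!fr %in% names(wide)) unique(wide$gene_id) else
        wide$gene_id[is.na(wide[[fr]])]
      abort(sprintf("missing %s Ct for gene(s): %s", fr,
                    paste(unique(bad), collapse = ", ")))
    }
  }
  ref <- wide %>% filter(.data$gene_id == reference)
  if (nrow(ref) == 0) {
    abort(sprintf("reference gene '%s' absent from the Ct table", reference))
  }
  wide %>%
    left_join(ref %>% select("replicate", ref_IP = "IP",
                             ref_input = "input"),
              by = "replicate") %>%
    mutate(ddct = (.data$IP - .data$ref_IP) -
             (.data$input - .data$ref_input),
           enr = 2 ^ (-.data$ddct)) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_replicates = n(),
      enrichment = 2 ^ mean(-.data$ddct),
      log2_sd = sd(-.data$ddct),
      replicate_enrichment = list(.data$enr),
      .groups = "drop"
    )
}

#' Direct RIP-qPCR enrichment without reference normalisation
#'
#' The protein-RIP formula `2^-(Ct_IP - Ct_input)`. Vectorised.
#'
#' @param ct_ip,ct_input Ct values, cycles.
#' @return Numeric enrichment values.
#' @examples
#' rip_enrichment_direct(28, 30)  # 4
#' @export
rip_enrichment_direct <- function(ct_ip, ct_input) {
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input))) {
    abort("Ct values must be finite")
  }
  2 ^ (-(ct_ip - ct_input))
}

#' Fit UHPLC-QQQ-MS/MS calibration curves for m6A and A
#'
#' Ordinary least-squares standard curves of peak area on concentration
#' (intercept free), one per analyte; quantification uses the nucleoside
#' to base ion transitions 282.1-150.1 (m6A) and 268.2-136.1 (A). A
#' log-space fit is available for dynamic ranges where multiplicative
#' error dominates.
#'
#' @param standards tibble: analyte (`m6A`/`A`), concentration, area; at
#'   least 3 standards per analyte.
#' @param log_space fit `log(area) ~ log(concentration)` instead.
#' @return Object of class `ms_calibration`: per-analyte slope, intercept,
#'   r_squared, range of standard concentrations, and `log_space`.
#' @export
ms_calibrate <- function(standards, log_space = FALSE) {
  assert_columns(standards, c("analyte", "concentration", "area"),
                 "standards")
  fits <- standards %>%
    group_by(.data$analyte) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        abort(sprintf("need >= 3 standards for analyte %s", key$analyte))
      }
      x <- df$concentration
      y <- df$area
      if (log_space) {
        x <- log(x)
        y <- log(y)
      }
      fit <- ols_line(x, y)
      if (fit$slope <= 0) {
        abort(sprintf("calibration slope for %s is not positive",
                      key$analyte))
      }
      tibble(slope = fit$slope, intercept = fit$intercept,
             r_squared = fit$r_squared,
             conc_min = min(df$concentration),
             conc_max = max(df$concentration))
    }) %>%
    ungroup()
  structure(list(fits = fits, log_space = log_space),
            class = "ms_calibration")
}

#' @export
print.ms_calibration <- function(x, ...) {
  cat("<ms_calibration>",
      if (x$log_space) "(log-space)" else "(linear)", "\n")
  print(x$fits)
  invisible(x)
}

#' m6A/A ratio from mass-spec peak areas
#'
#' Each nucleoside's concentration is read off its linear calibration
#' (`(area - intercept) / slope`, floored at 0 with a warning when the
#' area falls below the fitted intercept); the reported ratio is
#' `100 * [m6A] / [A]` in percent. Areas implying concentrations more than
#' 10x outside the standard range draw a warning.
#'
#' @param area_m6a,area_a sample peak areas for the two analytes.
#' @param calibration an [ms_calibrate()] object.
#' @return Tibble: conc_m6a, conc_a, ratio_pct.
#' @export
m6a_ratio_ms <- function(area_m6a, area_a, calibration) {
  stopifnot(inherits(calibration, "ms_calibration"))
  if (calibration$log_space) {
    invert <- function(area, f) exp((log(area) - f$intercept) / f$slope)
  } else {
    invert <- function(area, f) (area - f$intercept) / f$slope
  }
  one <- function(area, analyte) {
    f <- calibration$fits %>% filter(.data$analyte == !!analyte)
    if (nrow(f) == 0) abort(sprintf("no calibration for analyte %s", analyte))
    conc <- invert(area, f)
    if (any(conc < 0)) {
      warn(sprintf("%s area below fitted intercept; concentration floored at 0",
                   analyte))
      conc <- pmax(conc, 0)
    }
    out_of_range <- conc > 10 * f$conc_max |
      (conc > 0 & conc < f$conc_min / 10)
    if (any(out_of_range)) {
      warn(sprintf("%s concentration outside 10x the standard range",
                   analyte))
    }
    conc
  }
  cm <- one(area_m6a, "m6A")
  ca <- one(area_a, "A")
  if (any(ca <= 0)) abort("adenosine concentration must be positive")
  tibble(conc_m6a = cm, conc_a = ca, ratio_pct = 100 * cm / ca)
}
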