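# broom-style tidiers for the package's fitted objects

#' @describeIn calibrate_spikeins tidy coefficients of the calibration.
#' @param x a `spikein_calibration`.
#' @param ... unused.
#' @method tidy spikein_calibration
#' @export
tidy.spikein_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn calibrate_spikeins one-row fit summary.
#' @method glance spikein_calibration
#' @export
glance.spikein_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_spikeins_used = x$n_spikeins_used)
}

#' @describeIn fit_decay coefficients of the log-linear decay fit.
#' @param x a `decay_fit`.
#' @param ... unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("k_decay", "t_half"),
         estimate = c(x$k_decay, x$t_half),
         std.error = c(x$slope_se, NA_real_))
}

#' @describeIn fit_decay one-row fit summary.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(C0 = x$C0, k_decay = x$k_decay, t_half = x$t_half,
         slope_se = x$slope_se, r_squared = x$r_squared,
         n_timepoints_used = x$n_timepoints_used, flag = x$flag)
}

#' @describeIn compare_halflife_distributions per-gene paired half-lives.
#' @param x a `halflife_comparison`.
#' @param ... unused.
#' @method tidy halflife_comparison
#' @export
tidy.halflife_comparison <- function(x, ...) {
  tibble(median_a = x$median_a, median_b = x$median_b,
         U_statistic = x$U_statistic, p_value = x$p_value,
         n_a = x$n_a, n_b = x$n_b)
}

#' @describeIn compare_halflife_distributions same as `tidy()`.
#' @method glance halflife_comparison
#' @export
glance.halflife_comparison <- function(x, ...) tidy(x)

#' @describeIn screen_targets one row per candidate target gene.
#' @param x a `target_screen`.
#' @param ... unused.
#' @method tidy target_screen
#' @export
tidy.target_screen <- function(x, ...) {
  tibble(gene_id = x$targets)
}

#' @describeIn screen_targets set sizes of the screen.
#' @method glance target_screen
#' @export
glance.target_screen <- function(x, ...) {
  tibble(n_hyper = x$n_hyper, n_down = x$n_down, n_targets = x$n_targets)
}
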