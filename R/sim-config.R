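#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe a four-stage directed pancreatic differentiation (hPSC, definitive
#' endoderm, pancreatic progenitor, islet-like organoid) profiled by m6A-seq
#' with two biological replicates, and an actinomycin-D transcription-shutoff
#' decay course sampled at 0/1/2/3 h whose half-lives are log-normal with an
#' 8 h median. In the knockout-like condition, transcripts carrying m6A lose
#' 38% of their lifetime, the average reduction reported for demethylase-null
#' progenitors.
#'
#' @param n_genes number of genes (one transcript each).
#' @param n_stages number of differentiation stages; `stages` supplies labels.
#' @param stages character labels, length `n_stages`.
#' @param peak_rate mean number of true m6A peaks per gene (Poisson).
#' @param peak_width width of a true peak in nt.
#' @param window_size tiling window width in nt for windowed counting.
#' @param ip_enrichment fold enrichment of IP over input coverage inside true
#'   peaks; 1 gives null data.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param depth expected reads per library.
#' @param n_replicates biological replicates per library type.
#' @param halflife_median_h median of the log-normal true half-life
#'   distribution, hours.
#' @param halflife_sigma log-scale standard deviation of true half-lives.
#' @param m6a_lifetime_reduction fraction in [0, 1) by which m6A-tagged
#'   transcripts' half-lives shrink in the KO-like condition.
#' @param decay_stage stage whose expression and m6A status drive the decay
#'   course (the stage at which the shutoff experiment is performed).
#' @param peak_retention probability that a true peak present at one stage is
#'   retained at the next (drives inherited vs de novo structure).
#' @param n_spikeins number of ERCC-like spike-in species.
#' @param ct_noise_sd Gaussian technical noise on qPCR Ct values, cycles.
#' @param seed integer seed; a fixed seed makes every generator byte-identical.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' cfg$stages
#' @export
sim_config <- function(n_genes = 2000,
                       n_stages = 4,
                       stages = DEFAULT_STAGES,
                       peak_rate = 1,
                       peak_width = 200,
                       window_size = 50,
                       ip_enrichment = 10,
                       nb_dispersion = 0.02,
                       depth = 1e6,
                       n_replicates = 2,
                       halflife_median_h = 8,
                       halflife_sigma = 0.5,
                       m6a_lifetime_reduction = 0.38,
                       decay_stage = "PP",
                       peak_retention = 0.7,
                       n_spikeins = 24,
                       ct_noise_sd = 0.1,
                       seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_stages, "n_stages", min = 2)
  if (length(stages) != n_stages) {
    abort("`stages` must provide exactly `n_stages` labels")
  }
  if (anyDuplicated(stages)) abort("stage labels must be unique")
  assert_positive(peak_rate, "peak_rate", strict = FALSE)
  assert_count(peak_width, "peak_width")
  assert_count(window_size, "window_size")
  if (ip_enrichment < 1) abort("`ip_enrichment` must be >= 1")
  assert_positive(nb_dispersion, "nb_dispersion", strict = FALSE)
  assert_positive(depth, "depth")
  assert_count(n_replicates, "n_replicates")
  assert_positive(halflife_median_h, "halflife_median_h")
  assert_positive(halflife_sigma, "halflife_sigma", strict = FALSE)
  if (m6a_lifetime_reduction < 0 || m6a_lifetime_reduction >= 1) {
    abort("`m6a_lifetime_reduction` must lie in [0, 1)")
  }
  if (!decay_stage %in% stages) abort("`decay_stage` must be one of `stages`")
  if (peak_retention < 0 || peak_retention > 1) {
    abort("`peak_retention` must lie in [0, 1]")
  }
  assert_count(n_spikeins, "n_spikeins", min = 3)
  assert_positive(ct_noise_sd, "ct_noise_sd", strict = FALSE)
  assert_count(seed, "seed", min = -.Machine$integer.max)

  structure(
    list(
      n_genes = as.integer(n_genes), n_stages = as.integer(n_stages),
      stages = as.character(stages), peak_rate = peak_rate,
      peak_width = as.integer(peak_width),
      window_size = as.integer(window_size),
      ip_enrichment = ip_enrichment, nb_dispersion = nb_dispersion,
      depth = depth, n_replicates = as.integer(n_replicates),
      halflife_median_h = halflife_median_h, halflife_sigma = halflife_sigma,
      m6a_lifetime_reduction = m6a_lifetime_reduction,
      decay_stage = decay_stage, peak_retention = peak_retention,
      n_spikeins = as.integer(n_spikeins), ct_noise_sd = ct_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes x %d stages (%s), %d replicates\n",
              x$n_genes, x$n_stages, paste(x$stages, collapse = " -> "),
              x$n_replicates))
  cat(sprintf("  peaks: rate %.2f/gene, width %d nt, IP enrichment %.1fx\n",
              x$peak_rate, x$peak_width, x$ip_enrichment))
  cat(sprintf("  counts: depth %.3g, NB dispersion %.3g, windows %d nt\n",
              x$depth, x$nb_dispersion, x$window_size))
  cat(sprintf(
    "  decay: median t1/2 %.2g h (sigma %.2g), m6A lifetime reduction %.0f%%\n",
    x$halflife_median_h, x$halflife_sigma, 100 * x$m6a_lifetime_reduction))
  cat(sprintf("  %d spike-ins, Ct noise sd %.2g, seed %d\n",
              x$n_spikeins, x$ct_noise_sd, x$seed))
  invisible(x)
}
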