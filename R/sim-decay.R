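#' Simulate a transcription-shutoff decay time course
#'
#' Molar amounts decay exponentially from their initial value with each
#' gene's true condition-specific half-life; spike-ins keep constant known
#' attomole amounts. Each library (condition x replicate x timepoint) is
#' sequenced to the configured depth: read shares are proportional to
#' amount x length, and counts are negative-binomial around the expected
#' share (or exact expectations when `noise = FALSE`). Spike-in counts are
#' Poisson: the spike-ins are technical standards added at fixed amounts,
#' so they carry counting noise but no biological replicate-to-replicate
#' dispersion. Because later
#' timepoints contain less mRNA against a fixed sequencing depth, relative
#' units inflate over time and absolute recovery requires the spike-in
#' calibration — the situation the estimator is built for.
#'
#' @param truth a [simulate_truth()] object.
#' @param conditions subset of `c("WT", "KO")`.
#' @param timepoints sampling times after shutoff, hours.
#' @param noise if `FALSE`, expected counts are returned (real-valued).
#' @return A tibble of class `decay_course`: gene_id, condition, replicate,
#'   timepoint_h, count, length, is_spikein.
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 20, seed = 3))
#' course <- simulate_decay_course(truth, noise = FALSE)
#' @export
simulate_decay_course <- function(truth, conditions = c("WT", "KO"),
                                  timepoints = c(0, 1, 2, 3), noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  if (!all(conditions %in% unique(truth$halflives$condition))) {
    abort("`conditions` must be present in the simulated half-life truth")
  }
  if (any(timepoints < 0) || !0 %in% timepoints) {
    abort("`timepoints` must be non-negative and include 0")
  }
  if (any(truth$halflives$t_half <= 0)) {
    abort("ground-truth half-lives must be strictly positive")
  }

  tx <- truth$transcripts
  expr0 <- truth$expression %>%
    filter(.data$stage == config$decay_stage) %>%
    arrange(match(.data$gene_id, tx$gene_id))
  amount0 <- expr0$tpm * 1e-2  # attomoles at t = 0
  spike <- truth$spikeins

  with_sim_seed(config$seed, 505L, {
    purrr::map_dfr(conditions, function(cond) {
      th <- truth$halflives %>%
        filter(.data$condition == cond) %>%
        arrange(match(.data$gene_id, tx$gene_id)) %>%
        pull("t_half")
      purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
        purrr::map_dfr(timepoints, function(t) {
          amt <- c(amount0 * 2 ^ (-t / th), spike$attomoles)
          len <- c(tx$length, spike$length)
          ids <- c(tx$gene_id, spike$spikein_id)
          mu <- config$depth * (amt * len) / sum(amt * len)
          n_g <- nrow(tx)
          cnt <- if (noise) {
            c(rnb(n_g, mu[seq_len(n_g)], config$nb_dispersion),
              rpois(length(mu) - n_g, mu[-seq_len(n_g)]))
          } else mu
          tibble(gene_id = ids, condition = cond, replicate = rep_i,
                 timepoint_h = t, count = cnt, length = len,
                 is_spikein = grepl("^ERCC-", ids))
        })
      })
    }) %>%
      structure(class = c("decay_course", class(tibble())))
  })
}

#' Simulate an RT-qPCR Ct table for RIP enrichment assays
#'
#' Emulates an m6A-RIP-qPCR plate: each target gene's input abundance is its
#' stage TPM and its IP abundance is that abundance times the configured IP
#' enrichment when the gene is m6A-tagged at the stage (1x otherwise). A
#' GAPDH-like reference gene with no enrichment is always included. Ct
#' values follow `Ct = base - log2(relative abundance) + N(0, ct_noise_sd)`.
#'
#' @param truth a [simulate_truth()] object.
#' @param genes target genes; default: first 4 m6A-tagged genes at `stage`.
#' @param stage stage assayed; defaults to the configured decay stage.
#' @param n_replicates technical replicates per well.
#' @param base_ct Ct of a transcript at unit relative abundance.
#' @param reference id given to the reference (GAPDH-like) gene.
#' @param noise if `FALSE`, Ct values are exact.
#' @return Tibble: gene_id, fraction, replicate, ct; the reference gene id is
#'   attached as attribute `reference`.
#' @export
simulate_ct_table <- function(truth, genes = NULL, stage = NULL,
                              n_replicates = 3, base_ct = 30,
                              reference = "GAPDH", noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  stage <- stage %||% config$decay_stage
  if (!stage %in% config$stages) abort("unknown `stage`")
  status <- truth$m6a_status %>% filter(.data$stage == !!stage)
  if (is.null(genes)) {
    genes <- head(status$gene_id[status$m6a], 4)
    if (length(genes) == 0) abort("no m6A-tagged genes at this stage")
  }
  if (!all(genes %in% status$gene_id)) abort("unknown gene id in `genes`")

  expr <- truth$expression %>% filter(.data$stage == !!stage)
  ref_abund <- median(expr$tpm)
  abund <- c(expr$tpm[match(genes, expr$gene_id)], ref_abund)
  enr <- c(ifelse(status$m6a[match(genes, status$gene_id)],
                  config$ip_enrichment, 1), 1)
  ids <- c(genes, reference)

  with_sim_seed(config$seed, 606L, {
    out <- purrr::map_dfr(seq_along(ids), function(i) {
      purrr::map_dfr(c("input", "IP"), function(fr) {
        a <- if (fr == "IP") abund[i] * enr[i] else abund[i]
        ct0 <- base_ct - log2(a)
        tibble(gene_id = ids[i], fraction = fr,
               replicate = seq_len(n_replicates),
               ct = ct0 + if (noise) {
                 rnorm(n_replicates, 0, config$ct_noise_sd)
               } else 0)
      })
    })
    attr(out, "reference") <- reference
    out
  })
}
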