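#' Tile transcripts into counting windows
#'
#' Non-overlapping windows of `window_size` nt in transcript coordinates
#' (5' to 3'); the last partial window is kept. Genomic coordinates are
#' derived from the single-exon transcript span, 0-based half-open.
#'
#' @param transcripts transcript tibble as produced by
#'   [simulate_transcriptome()] or [read_gtf_segments()].
#' @param window_size window width, nt.
#' @return Tibble: window_id, gene_id, chrom, start, end, strand,
#'   tx_start, tx_end, width.
#' @export
tile_windows <- function(transcripts, window_size = 50) {
  assert_columns(transcripts,
                 c("gene_id", "chrom", "start", "end", "strand", "length"))
  assert_count(window_size, "window_size")
  transcripts %>%
    mutate(n_win = ceiling(.data$length / window_size)) %>%
    tidyr::uncount(.data$n_win, .id = "win") %>%
    mutate(
      tx_start = (.data$win - 1L) * window_size,
      tx_end = pmin(.data$win * window_size, .data$length),
      gstart = ifelse(.data$strand == "+",
                      .data$start + .data$tx_start,
                      .data$end - .data$tx_end),
      gend = ifelse(.data$strand == "+",
                    .data$start + .data$tx_end,
                    .data$end - .data$tx_start),
      window_id = sprintf("%s:w%04d", .data$gene_id, .data$win),
      width = .data$tx_end - .data$tx_start
    ) %>%
    select("window_id", "gene_id", "chrom", start = "gstart", end = "gend",
           "strand", "tx_start", "tx_end", "width")
}

#' Simulate windowed IP and input m6A-seq counts
#'
#' Draws negative-binomial counts for every window, library and replicate.
#' The expected input count of a window is proportional to the gene's read
#' share (TPM x length) times the window's fraction of the transcript; IP
#' windows overlapping a true peak occupied at that stage have their mean
#' multiplied by the IP fold-enrichment. `ip_enrichment = 1` yields null
#' data in which IP and input means are identical.
#'
#' @param truth a [simulate_truth()] object.
#' @param stages stages to simulate (default: all configured stages).
#' @param condition condition label stored in the sample metadata.
#' @param ip_enrichment fold enrichment inside occupied peaks; defaults to
#'   the configured value.
#' @param hyper_genes optional character vector of genes whose occupied peak
#'   windows receive `hyper_fold` times more IP enrichment (emulates
#'   demethylase-loss hyper-methylation).
#' @param hyper_fold extra IP fold applied to `hyper_genes`.
#' @param noise if `FALSE`, expected (real-valued) counts are returned.
#' @return A list: `windows` (window tibble), `counts` (long tibble:
#'   window_id, stage, condition, fraction, replicate, sample_id, count),
#'   `samples` (sample metadata with realised library sizes).
#' @export
simulate_m6a_counts <- function(truth, stages = NULL, condition = "WT",
                                ip_enrichment = NULL, hyper_genes = NULL,
                                hyper_fold = 2, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  stages <- stages %||% config$stages
  if (!all(stages %in% config$stages)) {
    abort("`stages` must be drawn from the configured stage labels")
  }
  ip_enrichment <- ip_enrichment %||% config$ip_enrichment
  if (!is.null(hyper_genes) &&
      !all(hyper_genes %in% truth$transcripts$gene_id)) {
    abort("`hyper_genes` contains ids absent from the simulated transcriptome")
  }

  windows <- tile_windows(truth$transcripts, config$window_size)
  tx <- truth$transcripts

  with_sim_seed(config$seed, 303L, {
    out <- purrr::map(stages, function(st) {
      expr <- truth$expression %>% filter(.data$stage == st)
      share <- expr$tpm * tx$length[match(expr$gene_id, tx$gene_id)]
      share <- share / sum(share)
      names(share) <- expr$gene_id

      base_mu <- config$depth * share[windows$gene_id] *
        windows$width / tx$length[match(windows$gene_id, tx$gene_id)]

      # windows whose transcript-coordinate span intersects an occupied peak
      occ <- truth$peaks %>%
        semi_join(truth$peak_stages %>% filter(.data$stage == st),
                  by = "peak_id") %>%
        select("gene_id", p_start = "tx_start", p_end = "tx_end")
      in_peak <- windows %>%
        mutate(.row = row_number()) %>%
        inner_join(occ, by = "gene_id",
                   relationship = "many-to-many") %>%
        filter(.data$tx_start < .data$p_end,
               .data$p_start < .data$tx_end) %>%
        pull(".row") %>% unique()

      fold <- rep(1, nrow(windows))
      fold[in_peak] <- ip_enrichment
      if (!is.null(hyper_genes)) {
        hyper_rows <- intersect(in_peak,
                                which(windows$gene_id %in% hyper_genes))
        fold[hyper_rows] <- fold[hyper_rows] * hyper_fold
      }

      purrr::map_dfr(c("input", "IP"), function(fr) {
        mu <- if (fr == "IP") base_mu * fold else base_mu
        purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
          cnt <- if (noise) rnb(length(mu), mu, config$nb_dispersion) else mu
          tibble(
            window_id = windows$window_id, stage = st,
            condition = condition, fraction = fr, replicate = rep_i,
            sample_id = sprintf("%s_%s_%s_rep%d", st, condition, fr, rep_i),
            count = cnt
          )
        })
      })
    })
    counts <- bind_rows(out)
    samples <- counts %>%
      group_by(.data$sample_id, .data$stage, .data$condition,
               .data$fraction, .data$replicate) %>%
      summarise(lib_size = sum(.data$count), .groups = "drop")
    list(windows = windows, counts = counts, samples = samples)
  })
}

#' Simulate transcript sequences with DRACH motifs planted at peak centers
#'
#' Random ACGT background with the canonical consensus 5-mer `GGACT`
#' written at every true peak center. Sequence realism beyond motif
#' placement is deliberately out of scope.
#'
#' @param truth a [simulate_truth()] object.
#' @return Tibble: gene_id, seq.
#' @export
simulate_sequences <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_sim_seed(truth$config$seed, 404L, {
    tx <- truth$transcripts
    seqs <- vapply(tx$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.28, 0.22, 0.22, 0.28)), collapse = "")
    }, character(1))
    for (j in seq_len(nrow(truth$peaks))) {
      i <- match(truth$peaks$gene_id[j], tx$gene_id)
      ctr <- truth$peaks$tx_center[j]
      lo <- max(1L, ctr - 1L)
      if (lo + 4L <= tx$length[i]) {
        substr(seqs[i], lo, lo + 4L) <- "GGACT"
      }
    }
    tibble(gene_id = tx$gene_id, seq = seqs)
  })
}

#' Simulate gene-level RNA-seq counts with optional planted fold changes
#'
#' Negative-binomial gene counts at one stage, with expected values
#' proportional to each gene's read share (TPM x length). A subset of
#' genes can be given a true fold change (`de_fold`), emulating the
#' expression consequences of a perturbation.
#'
#' @param truth a [simulate_truth()] object.
#' @param condition condition label.
#' @param stage stage whose expression profile is sampled; defaults to the
#'   configured decay stage.
#' @param de_genes genes whose expected expression is multiplied by
#'   `de_fold` (before library renormalisation).
#' @param de_fold linear fold change applied to `de_genes`.
#' @param noise if `FALSE`, expected counts are returned.
#' @param seed_offset change to draw an independent replicate set.
#' @return Long tibble: gene_id, condition, replicate, count.
#' @export
simulate_rnaseq_counts <- function(truth, condition = "WT", stage = NULL,
                                   de_genes = NULL, de_fold = 1,
                                   noise = TRUE, seed_offset = 0L) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  stage <- stage %||% config$decay_stage
  if (!stage %in% config$stages) abort("unknown `stage`")
  if (!is.null(de_genes) &&
      !all(de_genes %in% truth$transcripts$gene_id)) {
    abort("`de_genes` contains ids absent from the simulated transcriptome")
  }
  tx <- truth$transcripts
  expr <- truth$expression %>%
    filter(.data$stage == !!stage) %>%
    arrange(match(.data$gene_id, tx$gene_id))
  amount <- expr$tpm
  if (!is.null(de_genes)) {
    amount[expr$gene_id %in% de_genes] <-
      amount[expr$gene_id %in% de_genes] * de_fold
  }
  share <- amount * tx$length / sum(amount * tx$length)
  mu <- config$depth * share
  with_sim_seed(config$seed, 707L + seed_offset, {
    purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
      cnt <- if (noise) rnb(length(mu), mu, config$nb_dispersion) else mu
      tibble(gene_id = expr$gene_id, condition = condition,
             replicate = rep_i, count = cnt)
    })
  })
}
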