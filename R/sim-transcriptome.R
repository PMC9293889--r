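# Each generator draws from its own seed stream (config seed + fixed offset)
# and restores the caller's RNG state, so individual generators are
# reproducible in isolation and in any call order.
with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate a one-isoform-per-gene transcriptome with stage-wise expression
#'
#' Generates `n_genes` single-exon transcripts with positive-length 5'UTR,
#' CDS and 3'UTR segments laid out on synthetic chromosomes, and a
#' stage-by-gene TPM expression matrix. A small set of stage marker genes is
#' strongly upregulated at its own stage; every stage column sums to 1e6
#' (TPM convention).
#'
#' @param config a [sim_config()].
#' @return A list with elements `transcripts` (tibble: gene_id, chrom, start,
#'   end, strand, utr5_len, cds_len, utr3_len, length) and `expression`
#'   (tibble: gene_id, stage, tpm, marker).
#' @examples
#' tx <- simulate_transcriptome(sim_config(n_genes = 20, seed = 7))
#' tx$transcripts
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 101L, {
    n <- config$n_genes
    gene_id <- sprintf("gene%05d", seq_len(n))

    utr5_len <- sample(60:300, n, replace = TRUE)
    cds_len <- sample(300:1800, n, replace = TRUE)
    utr3_len <- sample(120:1200, n, replace = TRUE)
    len <- utr5_len + cds_len + utr3_len
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # sequential layout, ~200 genes per chromosome, 1 kb intergenic gaps
    per_chrom <- 200L
    chrom_idx <- (seq_len(n) - 1L) %/% per_chrom + 1L
    chrom <- sprintf("chr%d", chrom_idx)
    start <- integer(n)
    offset <- 0L
    for (i in seq_len(n)) {
      if (i > 1L && chrom_idx[i] != chrom_idx[i - 1L]) offset <- 0L
      start[i] <- offset
      offset <- offset + len[i] + 1000L
    }
    transcripts <- tibble(
      gene_id = gene_id, chrom = chrom,
      start = start, end = start + len, strand = strand,
      utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
      length = len
    )

    # baseline abundance log-normal; ~5% of genes marked per stage, 8x up
    base <- rlnorm(n, meanlog = log(30), sdlog = 1)
    n_marker <- max(1L, round(0.05 * n))
    marker_stage <- rep(NA_character_, n)
    pool <- sample(n)
    for (s in seq_along(config$stages)) {
      idx <- pool[((s - 1L) * n_marker + 1L):min(s * n_marker, n)]
      marker_stage[idx] <- config$stages[s]
    }
    expression <- purrr::map_dfr(config$stages, function(st) {
      fold <- ifelse(!is.na(marker_stage) & marker_stage == st, 8, 1)
      wobble <- rlnorm(n, meanlog = 0, sdlog = 0.3)
      tibble(
        gene_id = gene_id, stage = st,
        tpm = scale_to_tpm(base * fold * wobble),
        marker = !is.na(marker_stage) & marker_stage == st
      )
    })
    list(transcripts = transcripts, expression = expression)
  })
}

#' Simulate ground truth for every downstream observable
#'
#' Plants true m6A peaks on transcripts (Poisson number per gene, centers
#' biased towards CDS and 3'UTR), assigns each peak a contiguous run of
#' stages it occupies (birth stage plus geometric retention), derives the
#' per-stage m6A status of each gene, draws log-normal true half-lives for a
#' wild-type-like and a knockout-like condition (m6A-tagged transcripts at
#' `decay_stage` lose `m6a_lifetime_reduction` of their lifetime in the KO),
#' and fixes ERCC-like spike-in amounts spanning three orders of magnitude.
#'
#' @param config a [sim_config()].
#' @param transcriptome optional result of [simulate_transcriptome()]; when
#'   omitted it is generated from `config`.
#' @return A list of class `sim_truth`: `config`, `transcripts`, `expression`,
#'   `peaks` (tibble with genomic and transcript coordinates), `peak_stages`
#'   (long occupancy: peak_id, stage), `m6a_status` (gene_id, stage, m6a),
#'   `halflives` (gene_id, condition, t_half), `spikeins` (spikein_id,
#'   attomoles, length).
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 30, seed = 2))
#' head(truth$halflives)
#' @export
simulate_truth <- function(config, transcriptome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(transcriptome)) transcriptome <- simulate_transcriptome(config)
  tx <- transcriptome$transcripts

  with_sim_seed(config$seed, 202L, {
    n <- nrow(tx)
    n_peaks <- rpois(n, config$peak_rate)
    half_w <- config$peak_width %/% 2L

    peak_rows <- purrr::map_dfr(which(n_peaks > 0), function(i) {
      row <- tx[i, ]
      k <- n_peaks[i]
      # segment weights emulate the observed CDS/3'UTR (stop-codon) bias
      seg <- sample(c("utr5", "cds", "utr3"), k, replace = TRUE,
                    prob = c(0.10, 0.50, 0.40))
      seg_start <- c(utr5 = 0L,
                     cds = row$utr5_len,
                     utr3 = row$utr5_len + row$cds_len)
      seg_len <- c(utr5 = row$utr5_len, cds = row$cds_len,
                   utr3 = row$utr3_len)
      center <- seg_start[seg] +
        floor(runif(k, half_w, pmax(half_w + 1, seg_len[seg] - half_w)))
      center <- pmin(pmax(center, half_w), row$length - half_w - 1L)
      tibble(gene_id = row$gene_id, segment = seg,
             tx_center = as.integer(center))
    })

    if (nrow(peak_rows) > 0) {
      peak_rows <- peak_rows %>%
        left_join(tx, by = "gene_id") %>%
        mutate(
          tx_start = pmax(0L, .data$tx_center - half_w),
          tx_end = pmin(.data$length, .data$tx_center + half_w),
          gstart = ifelse(.data$strand == "+",
                          .data$start + .data$tx_start,
                          .data$end - .data$tx_end),
          gend = ifelse(.data$strand == "+",
                        .data$start + .data$tx_end,
                        .data$end - .data$tx_start)
        ) %>%
        arrange(.data$chrom, .data$gstart) %>%
        mutate(peak_id = sprintf("peak%05d", row_number())) %>%
        select(peak_id, gene_id = "gene_id", chrom = "chrom",
               start = "gstart", end = "gend", strand = "strand",
               segment = "segment", tx_start = "tx_start",
               tx_end = "tx_end", tx_center = "tx_center")
    } else {
      peak_rows <- tibble(peak_id = character(), gene_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          segment = character(), tx_start = integer(),
                          tx_end = integer(), tx_center = integer())
    }

    # occupancy: a birth stage, then geometric persistence through later stages
    stages <- config$stages
    peak_stages <- purrr::map_dfr(seq_len(nrow(peak_rows)), function(j) {
      birth <- sample(seq_along(stages), 1)
      keep <- birth
      s <- birth
      while (s < length(stages) && runif(1) < config$peak_retention) {
        s <- s + 1
        keep <- c(keep, s)
      }
      tibble(peak_id = peak_rows$peak_id[j], stage = stages[keep])
    })

    m6a_status <- tidyr::expand_grid(gene_id = tx$gene_id, stage = stages) %>%
      left_join(
        peak_stages %>%
          left_join(peak_rows %>% select("peak_id", "gene_id"),
                    by = "peak_id") %>%
          distinct(.data$gene_id, .data$stage) %>%
          mutate(m6a = TRUE),
        by = c("gene_id", "stage")
      ) %>%
      mutate(m6a = !is.na(.data$m6a))

    t_wt <- rlnorm(n, meanlog = log(config$halflife_median_h),
                   sdlog = config$halflife_sigma)
    tagged <- m6a_status %>%
      filter(.data$stage == config$decay_stage) %>%
      arrange(match(.data$gene_id, tx$gene_id)) %>%
      pull("m6a")
    t_ko <- ifelse(tagged, t_wt * (1 - config$m6a_lifetime_reduction), t_wt)
    halflives <- bind_rows(
      tibble(gene_id = tx$gene_id, condition = "WT", t_half = t_wt),
      tibble(gene_id = tx$gene_id, condition = "KO", t_half = t_ko)
    )

    spikeins <- tibble(
      spikein_id = sprintf("ERCC-%05d", seq_len(config$n_spikeins)),
      attomoles = 10 ^ seq(-1, 2, length.out = config$n_spikeins),
      length = sample(400:2000, config$n_spikeins, replace = TRUE)
    )

    structure(
      list(config = config, transcripts = tx,
           expression = transcriptome$expression,
           peaks = peak_rows, peak_stages = peak_stages,
           m6a_status = m6a_status, halflives = halflives,
           spikeins = spikeins),
      class = "sim_truth"
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d genes, %d true peaks, %d stages\n",
              nrow(x$transcripts), nrow(x$peaks), x$config$n_stages))
  cat(sprintf("  m6A-tagged at %s: %d genes\n", x$config$decay_stage,
              sum(x$m6a_status$m6a[x$m6a_status$stage ==
                                     x$config$decay_stage])))
  invisible(x)
}
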