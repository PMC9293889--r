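#' Run the integrated target-screening pipeline on synthetic data
#'
#' End-to-end orchestration of the package on one simulated experiment:
#' ground truth is generated, m6A-seq window counts are simulated for a
#' wild-type-like and a hyper-methylated knockout-like condition, peaks
#' are called, differential methylation and differential expression are
#' tested, hyper-methylated and downregulated genes are intersected into
#' the candidate target set, and (optionally) decay courses are fitted
#' into half-life tables and compared. Every output is written under
#' `outdir` together with a JSON manifest recording the configuration,
#' seed, thresholds and file checksums.
#'
#' @param sim a [sim_config()] describing the synthetic experiment.
#' @param run a [run_config()] of analysis thresholds.
#' @param outdir output directory (created if missing).
#' @param halflife also run the decay/half-life arm.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(sim = sim_config(n_genes = 300),
                        run = run_config(), outdir = tempfile("m6adyn_"),
                        halflife = TRUE) {
  stopifnot(inherits(sim, "sim_config"), inherits(run, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "m6adyn",
    version = as.character(utils::packageVersion("m6adyn")),
    seed = sim$seed,
    sim_config = unclass(sim),
    run_config = unclass(run),
    outputs = list(),
    status = "incomplete"
  )
  results <- list()
  emit <- function(obj, file, writer = readr::write_tsv) {
    p <- file.path(outdir, file)
    writer(obj, p)
    manifest$outputs[[file]] <<- list(path = file,
                                      md5 = unname(tools::md5sum(p)))
    p
  }
  finish <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  res <- tryCatch({
    truth <- simulate_truth(sim)
    results$truth <- truth
    emit(truth$transcripts, "transcripts.tsv")
    write_gtf(truth$transcripts, file.path(outdir, "transcripts.gtf"))
    manifest$outputs[["transcripts.gtf"]] <- list(
      path = "transcripts.gtf",
      md5 = unname(tools::md5sum(file.path(outdir, "transcripts.gtf"))))
    if (nrow(truth$peaks) > 0) {
      emit(truth$peaks, "true_peaks.tsv")
    }

    # m6A-seq arm at the perturbation stage: WT vs hyper-methylated KO
    st <- sim$decay_stage
    tagged <- truth$m6a_status %>%
      filter(.data$stage == st, .data$m6a) %>% pull("gene_id")
    # perturb a modest subset of tagged genes: gain of methylation plus loss
    # of expression, the signature the screen is built to recover
    planted <- head(tagged, min(length(tagged), ceiling(0.1 * sim$n_genes)))
    wt <- simulate_m6a_counts(truth, stages = st, condition = "WT")
    ko <- simulate_m6a_counts(truth, stages = st, condition = "KO",
                              hyper_genes = planted, hyper_fold = 4)
    called <- call_peaks(wt$counts, wt$windows,
                         ratio_min = run$peak_ratio, p_max = run$peak_p)
    results$peaks <- called
    if (nrow(called$peaks) > 0) {
      write_bed(called$peaks %>% mutate(name = .data$peak_id),
                file.path(outdir, "peaks_WT.bed"))
      manifest$outputs[["peaks_WT.bed"]] <- list(
        path = "peaks_WT.bed",
        md5 = unname(tools::md5sum(file.path(outdir, "peaks_WT.bed"))))
    }
    called_ko <- call_peaks(ko$counts, ko$windows,
                            ratio_min = run$peak_ratio, p_max = run$peak_p)
    # union of WT and KO called peaks, overlaps merged per gene
    union_peaks <- bind_rows(called$peaks, called_ko$peaks) %>%
      arrange(.data$gene_id, .data$start) %>%
      group_by(.data$gene_id) %>%
      mutate(run = cumsum(.data$start >
                            dplyr::lag(cummax(.data$end), default = -1L))) %>%
      group_by(.data$gene_id, .data$run) %>%
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                .groups = "drop") %>%
      select(-"run") %>%
      mutate(peak_id = sprintf("union%05d", row_number()))
    diff <- differential_peaks(wt$counts, ko$counts, wt$windows,
                               peaks = union_peaks,
                               lfc_min = run$diff_lfc,
                               alpha = run$diff_alpha)
    results$differential_peaks <- diff
    emit(diff$tests, "differential_peaks.tsv")

    # expression arm: planted 4-fold drop on the m6A-tagged genes
    rna_wt <- simulate_rnaseq_counts(truth, condition = "WT")
    rna_ko <- simulate_rnaseq_counts(truth, condition = "KO",
                                     de_genes = planted, de_fold = 0.25,
                                     seed_offset = 1L)
    de <- differential_expression(bind_rows(rna_wt, rna_ko),
                                  condition_a = "WT", condition_b = "KO",
                                  alpha = run$de_alpha,
                                  fc_up = run$de_fc_up,
                                  fc_down = run$de_fc_down)
    results$de <- de
    emit(de, "differential_expression.tsv")

    screen <- screen_targets(
      diff$hyper_genes,
      de %>% filter(.data$label == "down") %>% pull("gene_id"))
    results$screen <- screen
    emit(tibble(gene_id = screen$targets), "targets.tsv")

    if (halflife) {
      course <- simulate_decay_course(truth)
      emit(course, "decay_course.tsv", writer = write_course_tsv)
      tables <- purrr::map(
        c(WT = "WT", KO = "KO"),
        function(cond) estimate_halflives(
          course %>% filter(.data$condition == cond),
          spikeins = truth$spikeins, tpm_min = run$tpm_min))
      results$halflives <- tables
      emit(bind_rows(tables), "halflives.tsv")
      cmp <- compare_halflife_distributions(tables$WT, tables$KO)
      results$comparison <- cmp
      jsonlite::write_json(
        tidy(cmp), file.path(outdir, "halflife_comparison.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$outputs[["halflife_comparison.json"]] <- list(
        path = "halflife_comparison.json",
        md5 = unname(tools::md5sum(
          file.path(outdir, "halflife_comparison.json"))))
    }
    finish("complete")
    results$manifest <- manifest
    results
  }, error = function(e) {
    finish(paste("failed:", conditionMessage(e)))
    abort(sprintf("pipeline failed (partial outputs kept in %s): %s",
                  outdir, conditionMessage(e)))
  })
  invisible(res)
}
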