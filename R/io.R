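# readers/writers for BED, GTF and the package's TSV tables; all genomic
# coordinates are 0-based half-open internally (BED convention), GTF is
# converted at the boundary

#' Read peaks from a BED file
#'
#' Accepts BED3, BED6 and BED6+2 (extra columns: gene_id, p_value).
#' Records with start >= end are rejected and logged with their line
#' number; a `.` strand is treated as `+` with a warning.
#'
#' @param path BED file path.
#' @return Peak tibble: chrom, start, end, name, score, strand (and
#'   gene_id, p_value for BED6+2); attribute `n_rejected`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  usable <- nf >= 3
  ncol_use <- min(max(nf[usable]), 8L)
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
           character(1))
  }
  df <- tibble(
    chrom = get_col(1),
    start = suppressWarnings(as.integer(get_col(2))),
    end = suppressWarnings(as.integer(get_col(3)))
  )
  if (ncol_use >= 6) {
    df$name <- get_col(4)
    df$score <- suppressWarnings(as.numeric(get_col(5)))
    df$strand <- get_col(6)
  } else {
    df$name <- "."
    df$score <- 0
    df$strand <- "."
  }
  if (ncol_use >= 8) {
    df$gene_id <- get_col(7)
    df$p_value <- suppressWarnings(as.numeric(get_col(8)))
  }
  bad <- !usable | is.na(df$start) | is.na(df$end) | df$start >= df$end
  if (any(bad)) {
    warn(sprintf("rejected %d malformed BED record(s) at line(s): %s",
                 sum(bad),
                 paste(head(which(bad), 10), collapse = ", ")))
  }
  df <- df[!bad, , drop = FALSE]
  if (any(df$strand == ".")) {
    warn("strand '.' treated as '+'")
    df$strand[df$strand == "."] <- "+"
  }
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Write peaks to a BED6(+2) file
#'
#' @param peaks peak tibble (chrom, start, end; optional name, score,
#'   strand, gene_id, p_value).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  assert_columns(peaks, c("chrom", "start", "end"), "peaks")
  name <- peaks$name %||% peaks$peak_id %||% rep(".", nrow(peaks))
  score <- peaks$score %||% rep(0, nrow(peaks))
  strand <- peaks$strand %||% rep("+", nrow(peaks))
  fmt <- function(x) vapply(x, function(v) format(v, trim = TRUE),
                            character(1))
  cols <- list(peaks$chrom, peaks$start, peaks$end, name, fmt(score),
               strand)
  if (all(c("gene_id", "p_value") %in% names(peaks))) {
    cols <- c(cols, list(peaks$gene_id, fmt(peaks$p_value)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read simplified transcript models from a GTF file
#'
#' Imports exon/CDS/UTR features, keeps the longest transcript of each
#' gene (summed exon length; the standard longest-isoform rule), converts
#' 1-based inclusive GTF coordinates to 0-based half-open, and derives
#' 5'UTR/CDS/3'UTR segment lengths. A transcript without an annotated CDS
#' is treated as all-CDS and flagged.
#'
#' @param path GTF file path.
#' @return Transcript tibble: gene_id, transcript_id, chrom, start, end,
#'   strand, utr5_len, cds_len, utr3_len, length, flag.
#' @export
read_gtf_segments <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr)) %>%
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  if (!"transcript_id" %in% names(df)) {
    df$transcript_id <- df$gene_id
  }
  ex <- df %>% filter(.data$type == "exon")
  if (nrow(ex) == 0) abort("GTF contains no exon features")

  tx_len <- ex %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(exon_len = sum(.data$width),
              chrom = first(.data$chrom),
              gstart = min(.data$start) - 1L,  # to 0-based half-open
              gend = max(.data$end),
              strand = first(.data$strand), .groups = "drop")
  keep <- tx_len %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$exon_len), .data$transcript_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  seg_len <- function(types) {
    df %>%
      filter(.data$type %in% types) %>%
      group_by(.data$transcript_id) %>%
      summarise(len = sum(.data$width), .groups = "drop")
  }
  u5 <- seg_len(c("five_prime_utr", "5UTR"))
  cds <- seg_len("CDS")
  u3 <- seg_len(c("three_prime_utr", "3UTR"))

  keep %>%
    left_join(u5 %>% rename(utr5_len = "len"), by = "transcript_id") %>%
    left_join(cds %>% rename(cds_len = "len"), by = "transcript_id") %>%
    left_join(u3 %>% rename(utr3_len = "len"), by = "transcript_id") %>%
    mutate(
      flag = ifelse(is.na(.data$cds_len), "no_cds", "ok"),
      cds_len = ifelse(is.na(.data$cds_len), .data$exon_len,
                       .data$cds_len),
      utr5_len = tidyr::replace_na(.data$utr5_len, 0L),
      utr3_len = tidyr::replace_na(.data$utr3_len, 0L),
      length = .data$exon_len
    ) %>%
    select("gene_id", "transcript_id", "chrom", start = "gstart",
           end = "gend", "strand", "utr5_len", "cds_len", "utr3_len",
           "length", "flag")
}

#' Write simplified transcript models as GTF
#'
#' Emits exon, five_prime_utr, CDS and three_prime_utr features per
#' single-exon transcript, 1-based inclusive per the GTF standard.
#'
#' @param transcripts transcript tibble (as from
#'   [simulate_transcriptome()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  assert_columns(transcripts,
                 c("gene_id", "chrom", "start", "end", "strand",
                   "utr5_len", "cds_len", "utr3_len"), "transcripts")
  rows <- purrr::pmap(transcripts, function(gene_id, chrom, start, end,
                                            strand, utr5_len, cds_len,
                                            utr3_len, ...) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.1";', gene_id,
                     gene_id)
    # segment boundaries in genomic coordinates, strand-aware
    if (strand == "+") {
      b <- start + cumsum(c(0L, utr5_len, cds_len, utr3_len))
      seg <- c("five_prime_utr", "CDS", "three_prime_utr")
      s <- b[1:3]; e <- b[2:4]
    } else {
      b <- end - cumsum(c(0L, utr5_len, cds_len, utr3_len))
      seg <- c("five_prime_utr", "CDS", "three_prime_utr")
      s <- b[2:4]; e <- b[1:3]
    }
    feat <- c("exon", seg)
    fs <- c(start, s)
    fe <- c(end, e)
    sprintf("%s\tm6adyn\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, fs + 1L, fe, strand, attrs)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write / read a decay course as wide TSV
#'
#' The on-disk layout has one row per gene x condition x replicate with
#' timepoint columns `t0,t1,...` (counts); spike-in rows carry the `ERCC-`
#' id prefix. A `length` column preserves effective lengths for TPM.
#'
#' @param course long decay-course tibble.
#' @param path file path.
#' @return `path` invisibly (writer); long course tibble (reader).
#' @export
write_course_tsv <- function(course, path) {
  assert_columns(course, c("gene_id", "condition", "replicate",
                           "timepoint_h", "count", "length"), "course")
  wide <- course %>%
    mutate(tp = sprintf("t%g", .data$timepoint_h)) %>%
    select("gene_id", "condition", "replicate", "length", "tp", "count") %>%
    tidyr::pivot_wider(names_from = "tp", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_course_tsv
#' @export
read_course_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(wide, c("gene_id", "condition", "replicate", "length"),
                 "course TSV")
  tp_cols <- grep("^t[0-9.]+$", names(wide), value = TRUE)
  if (length(tp_cols) == 0) abort("no timepoint columns (t0, t1, ...) found")
  wide %>%
    tidyr::pivot_longer(all_of(tp_cols), names_to = "tp",
                        values_to = "count") %>%
    mutate(timepoint_h = as.numeric(sub("^t", "", .data$tp)),
           is_spikein = grepl("^ERCC-", .data$gene_id)) %>%
    select("gene_id", "condition", "replicate", "timepoint_h", "count",
           "length", "is_spikein")
}

#' Analysis thresholds and run settings
#'
#' Default thresholds follow the standard published settings of this
#' analysis family: peak windows at IP/input ratio 1.5 and p < 1e-5,
#' differential peaks at |log2FC| >= 1 and adjusted p < 0.05, differential
#' expression at FC > 1.5 or < 0.67 and adjusted p < 0.05, a TPM > 5
#' expression filter, inheritance overlap > 0.5, and |r| > 0.5 with
#' p < 0.05 for m6A-expression correlation.
#'
#' @param peak_ratio,peak_p window peak-calling thresholds.
#' @param diff_lfc,diff_alpha differential-methylation thresholds.
#' @param de_fc_up,de_fc_down,de_alpha differential-expression thresholds.
#' @param tpm_min expression filter.
#' @param overlap_min inheritance/origin overlap fraction.
#' @param cor_r,cor_alpha m6A-expression correlation thresholds.
#' @param seed integer seed for any simulation steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(peak_ratio = 1.5, peak_p = 1e-5, diff_lfc = 1,
                       diff_alpha = 0.05, de_fc_up = 1.5,
                       de_fc_down = 0.67, de_alpha = 0.05, tpm_min = 5,
                       overlap_min = 0.5, cor_r = 0.5, cor_alpha = 0.05,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys error,
#' missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown run_config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}
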