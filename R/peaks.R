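# peaks are tibbles with chrom, start, end (0-based half-open), strand,
# and usually gene_id, stage, score, p_value

peaks_to_granges <- function(peaks) {
  assert_columns(peaks, c("chrom", "start", "end"), "peaks")
  if (any(peaks$start >= peaks$end)) {
    abort("peak intervals must satisfy start < end")
  }
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "*"
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = strand
  )
}

#' Fraction of a query peak covered by another peak
#'
#' `|a intersect b| / |a|`: the denominator is always the query peak `a`.
#' Peaks on different chromosomes or strands do not overlap. Vectorised
#' elementwise over the rows of two equally sized peak tibbles.
#'
#' @param a,b peak tibbles (chrom, start, end, strand) with equal row
#'   counts, 0-based half-open coordinates.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200, strand = "+")
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250, strand = "+")
#' overlap_fraction(a, b)  # 0.5
#' @export
overlap_fraction <- function(a, b) {
  assert_columns(a, c("chrom", "start", "end"), "a")
  assert_columns(b, c("chrom", "start", "end"), "b")
  if (nrow(a) != nrow(b)) abort("`a` and `b` must have the same row count")
  same <- a$chrom == b$chrom
  if ("strand" %in% names(a) && "strand" %in% names(b)) {
    same <- same & a$strand == b$strand
  }
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(same, ov / (a$end - a$start), 0)
}

# For every peak in `query`, the best (max overlap-fraction) hit in `subject`.
# Returns per-query best fraction, reciprocal fraction and subject index
# (ties broken by subject coordinate order).
best_overlap <- function(query, subject) {
  n <- nrow(query)
  res <- tibble(frac = rep(0, n), frac_rev = rep(0, n),
                subject_idx = rep(NA_integer_, n))
  if (n == 0 || nrow(subject) == 0) return(res)
  subject <- subject %>% arrange(.data$chrom, .data$start, .data$end)
  gq <- peaks_to_granges(query)
  gs <- peaks_to_granges(subject)
  hits <- GenomicRanges::findOverlaps(gq, gs, ignore.strand = FALSE)
  if (length(hits) == 0) return(res)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  frac <- inter / (query$end[qi] - query$start[qi])
  frac_rev <- inter / (subject$end[si] - subject$start[si])
  # best hit per query; ties by subject coordinate order (si ascending)
  ord <- order(qi, -frac, si)
  keep <- !duplicated(qi[ord])
  sel <- ord[keep]
  res$frac[qi[sel]] <- frac[sel]
  res$frac_rev[qi[sel]] <- frac_rev[sel]
  res$subject_idx[qi[sel]] <- si[sel]
  res$subject_id <- NA_character_
  if ("peak_id" %in% names(subject)) {
    res$subject_id <- subject$peak_id[res$subject_idx]
  }
  res
}

#' Classify a stage's peaks as inherited or de novo
#'
#' A peak is `inherited` when more than 50% of its span is covered by some
#' peak of the previous stage (strictly greater, query-denominated;
#' `reciprocal = TRUE` additionally requires >50% of the previous-stage
#' peak to be covered). Peaks on transcripts whose expression does not
#' exceed `tpm_min` at the current stage are excluded before labelling.
#'
#' @param current,previous peak tibbles for the current and previous stage.
#' @param expression optional tibble (gene_id, tpm) of current-stage
#'   expression used for the TPM filter; `NULL` disables the filter.
#' @param tpm_min expression cutoff (strict: kept when TPM > `tpm_min`).
#' @param min_overlap overlap fraction that must be exceeded.
#' @param reciprocal require the overlap criterion in both directions.
#' @return A list: `labels` (current peaks with columns label,
#'   overlap_frac, source_peak) and `summary` (n, percent per label).
#' @export
classify_inheritance <- function(current, previous, expression = NULL,
                                 tpm_min = 5, min_overlap = 0.5,
                                 reciprocal = FALSE) {
  if (nrow(current) == 0) {
    warn("current stage has no peaks; returning empty labelling")
    return(list(labels = current, summary = tibble()))
  }
  if (!is.null(expression)) {
    assert_columns(expression, c("gene_id", "tpm"), "expression")
    assert_columns(current, "gene_id", "current")
    keep_genes <- expression$gene_id[expression$tpm > tpm_min]
    current <- current %>% filter(.data$gene_id %in% keep_genes)
    if (nrow(current) == 0) {
      warn("no current-stage peaks survive the TPM filter")
      return(list(labels = current, summary = tibble()))
    }
  }
  bo <- best_overlap(current, previous)
  inherited <- bo$frac > min_overlap &
    (!reciprocal | bo$frac_rev > min_overlap)
  labels <- current %>%
    mutate(label = ifelse(inherited, "inherited", "de_novo"),
           overlap_frac = bo$frac,
           source_peak = ifelse(inherited, bo$subject_id, NA_character_))
  summary <- labels %>%
    count(.data$label) %>%
    tidyr::complete(label = c("inherited", "de_novo"),
                    fill = list(n = 0L)) %>%
    mutate(percent = 100 * .data$n / sum(.data$n))
  list(labels = labels, summary = summary)
}

#' Trace the stage of origin of every peak
#'
#' For each peak of each stage, earlier stages are checked in
#' differentiation order; the earliest stage whose peak set covers more
#' than `min_overlap` of the peak is its origin. A peak matching no earlier
#' stage originates at its own stage. The first-match cascade removes peaks
#' already attributed to earlier origins, so origins partition each stage's
#' peaks.
#'
#' @param stage_peaks named list of peak tibbles in differentiation order
#'   (earliest first), or a single tibble with a `stage` column plus
#'   `stage_order` giving the order.
#' @param stage_order stage labels in order when `stage_peaks` is a tibble.
#' @param min_overlap overlap fraction that must be exceeded.
#' @return A list: `peaks` (all peaks with stage and origin columns) and
#'   `summary` (per stage, fraction of peaks per origin).
#' @export
trace_origin <- function(stage_peaks, stage_order = NULL,
                         min_overlap = 0.5) {
  if (is.data.frame(stage_peaks)) {
    assert_columns(stage_peaks, "stage", "stage_peaks")
    stage_order <- stage_order %||% unique(stage_peaks$stage)
    stage_peaks <- purrr::map(
      setNames(stage_order, stage_order),
      function(s) stage_peaks %>% filter(.data$stage == s)
    )
  }
  if (length(stage_peaks) < 2) abort("need at least 2 stages")
  stages <- names(stage_peaks) %||% as.character(seq_along(stage_peaks))

  out <- purrr::imap(stage_peaks, function(pk, st) {
    i <- match(st, stages)
    if (nrow(pk) == 0) return(pk %>% mutate(stage = character(0),
                                            origin = character(0)))
    origin <- rep(NA_character_, nrow(pk))
    for (j in seq_len(i - 1)) {
      unresolved <- is.na(origin)
      if (!any(unresolved)) break
      bo <- best_overlap(pk[unresolved, , drop = FALSE], stage_peaks[[j]])
      hit <- bo$frac > min_overlap
      origin[which(unresolved)[hit]] <- stages[j]
    }
    origin[is.na(origin)] <- st
    pk %>% mutate(stage = st, origin = origin)
  })
  peaks <- bind_rows(out)
  summary <- peaks %>%
    count(.data$stage, .data$origin) %>%
    group_by(.data$stage) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(stage = factor(.data$stage, levels = stages),
           origin = factor(.data$origin, levels = stages)) %>%
    arrange(.data$stage, .data$origin)
  list(peaks = peaks, summary = summary)
}

#' Bin genes by their number of m6A peaks
#'
#' Genes are classified into the categories 0-1, 2-4 and >=5 peaks. When a
#' `stage` column is present, binning is per stage. Peaks whose gene id is
#' not in `genes` are tallied under the sentinel `<unknown>` and reported.
#'
#' @param peaks peak tibble carrying gene_id (and optionally stage).
#' @param genes character vector of all gene ids (zero-peak genes are
#'   counted in the 0-1 bin).
#' @return A list: `genes` (per gene: n_peaks, bin) and `summary` (per
#'   stage and bin: n, fraction); attribute `n_unknown` counts orphan peaks.
#' @export
bin_genes_by_peak_count <- function(peaks, genes) {
  assert_columns(peaks, "gene_id", "peaks")
  has_stage <- "stage" %in% names(peaks)
  unknown <- sum(!peaks$gene_id %in% genes)
  if (unknown > 0) {
    warn(sprintf("%d peak(s) reference unknown gene ids; tallied as <unknown>",
                 unknown))
  }
  peaks <- peaks %>%
    mutate(gene_id = ifelse(.data$gene_id %in% genes, .data$gene_id,
                            "<unknown>"))
  grid <- if (has_stage) {
    tidyr::expand_grid(gene_id = genes, stage = unique(peaks$stage))
  } else {
    tibble(gene_id = genes)
  }
  keys <- if (has_stage) c("gene_id", "stage") else "gene_id"
  per_gene <- peaks %>%
    filter(.data$gene_id != "<unknown>") %>%
    count(across(all_of(keys)), name = "n_peaks") %>%
    dplyr::right_join(grid, by = keys) %>%
    mutate(n_peaks = tidyr::replace_na(.data$n_peaks, 0L),
           bin = cut(.data$n_peaks, c(-Inf, 1, 4, Inf),
                     labels = c("0-1", "2-4", ">=5")))
  stage_key <- intersect("stage", names(per_gene))
  summary <- per_gene %>%
    group_by(across(all_of(stage_key)), .data$bin, .drop = FALSE) %>%
    summarise(n = n(), .groups = "drop_last") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  res <- list(genes = per_gene, summary = summary)
  attr(res, "n_unknown") <- unknown
  res
}

#' Metagene distribution of peaks along 5'UTR / CDS / 3'UTR
#'
#' Each peak's midpoint is mapped to a position on a normalised transcript
#' axis: the 5'UTR, CDS and 3'UTR each span one unit, so the axis runs from
#' 0 to 3 with segment boundaries at 1 and 2. The histogram density
#' integrates to 1. Peaks whose midpoint falls outside their transcript are
#' skipped and counted.
#'
#' @param peaks peak tibble with gene_id and genomic coordinates.
#' @param transcripts transcript models with segment lengths.
#' @param n_bins_per_segment histogram bins per segment.
#' @return A tibble of class `m6a_metagene`: bin_start, bin_mid, segment,
#'   count, density; attribute `n_skipped`.
#' @export
metagene_distribution <- function(peaks, transcripts,
                                  n_bins_per_segment = 30) {
  assert_columns(peaks, c("gene_id", "chrom", "start", "end"), "peaks")
  assert_columns(transcripts,
                 c("gene_id", "start", "end", "strand",
                   "utr5_len", "cds_len", "utr3_len", "length"),
                 "transcripts")
  if (any(transcripts$utr5_len <= 0 | transcripts$cds_len <= 0 |
            transcripts$utr3_len <= 0)) {
    abort("transcript segments must have positive lengths")
  }
  tx <- transcripts
  i <- match(peaks$gene_id, tx$gene_id)
  mid <- (peaks$start + peaks$end) / 2
  # genomic midpoint -> transcript coordinate (5' -> 3')
  tpos <- ifelse(tx$strand[i] == "+", mid - tx$start[i], tx$end[i] - mid)
  inside <- !is.na(tpos) & tpos >= 0 & tpos < tx$length[i]
  n_skipped <- sum(!inside)
  if (n_skipped > 0) {
    inform(sprintf("%d peak(s) outside annotated transcripts skipped",
                   n_skipped))
  }
  tpos <- tpos[inside]
  ii <- i[inside]
  u5 <- tx$utr5_len[ii]
  cds <- tx$cds_len[ii]
  u3 <- tx$utr3_len[ii]
  x <- ifelse(
    tpos < u5, tpos / u5,
    ifelse(tpos < u5 + cds, 1 + (tpos - u5) / cds,
           2 + (tpos - u5 - cds) / u3)
  )
  nb <- 3L * n_bins_per_segment
  breaks <- seq(0, 3, length.out = nb + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = nb)
  bw <- 3 / nb
  out <- tibble(
    bin_start = breaks[-(nb + 1)],
    bin_mid = breaks[-(nb + 1)] + bw / 2,
    segment = rep(c("5'UTR", "CDS", "3'UTR"), each = n_bins_per_segment),
    count = counts,
    density = if (sum(counts) > 0) counts / sum(counts) / bw else 0
  )
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("m6a_metagene", class(out))
  out
}
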