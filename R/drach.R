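#' Scan sequences for the DRACH m6A consensus motif
#'
#' Finds every (possibly overlapping) occurrence of the degenerate 5-mer
#' DRACH (D = A/G/U, R = A/G, H = A/C/U) on the given strand of each
#' sequence. RNA and DNA alphabets are accepted (U and T are equivalent);
#' positions holding any other character simply cannot match.
#'
#' @param sequences character vector of sequences; names (or a tibble with
#'   columns `gene_id`/`name` and `seq`) identify them.
#' @return Tibble: name, pos (1-based start of the 5-mer), motif. Zero rows
#'   when nothing matches.
#' @examples
#' scan_drach(c(x = "GGACU"))  # one hit at position 1
#' @export
scan_drach <- function(sequences) {
  if (is.data.frame(sequences)) {
    nm_col <- intersect(c("gene_id", "name"), names(sequences))[1]
    if (is.na(nm_col) || !"seq" %in% names(sequences)) {
      abort("a sequence tibble needs a `gene_id` (or `name`) and a `seq` column")
    }
    seqs <- setNames(sequences$seq, sequences[[nm_col]])
  } else {
    seqs <- sequences
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  }
  norm <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  pat <- "(?=[AGT][AG]AC[ACT])"  # lookahead: overlapping matches allowed
  purrr::imap_dfr(norm, function(s, nm) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) return(tibble(name = character(), pos = integer(),
                                  motif = character()))
    tibble(name = nm, pos = as.integer(m),
           motif = substring(s, m, m + 4L))
  })
}
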