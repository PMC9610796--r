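PROMOTER_MOTIFS <- c(C = "CA[GT]T", L = "TAAG", T = "TATAA")

#' Scan for early/late promoter motifs upstream of ORFs
#'
#' Searches the `window` bp immediately 5' of the start codon on each ORF's
#' coding strand (the reverse complement of the downstream flank for
#' minus-strand ORFs; the search wraps on circular genomes). Labels follow
#' the convention used in alphabaculovirus annotation tables: `C` for the
#' early motif CAKT (K = G or T), `L` for the late motif TAAG, and `T` for
#' the early TATA motif TATAA. Motif occurrences may overlap.
#'
#' @param genome An [genome()] object.
#' @param orfs ORF tibble (needs `start`, `end`, `strand`; `orf_id` carried
#'   through if present).
#' @param window Upstream window in bp (default 200). On a linear genome a
#'   window running past the sequence end is truncated with a warning.
#' @return A tibble with one row per ORF: `orf_id`, `start`, `end`, `strand`,
#'   `labels` (comma-joined in C,L,T order, `""` if none) and logical columns
#'   `C`, `L`, `T`.
#' @export
scan_promoters <- function(genome, orfs, window = 200L) {
  orfs <- tibble::as_tibble(orfs)
  res <- purrr::map(seq_len(nrow(orfs)), function(i) {
    up <- upstream_window(genome, orfs$start[i], orfs$end[i],
                          orfs$strand[i], window)
    hits <- vapply(PROMOTER_MOTIFS, function(m) grepl(m, up), logical(1))
    tibble::tibble(C = hits[["C"]], L = hits[["L"]], T = hits[["T"]])
  })
  res <- dplyr::bind_rows(res)
  tibble::tibble(
    orf_id = if ("orf_id" %in% names(orfs)) orfs$orf_id else NA_integer_,
    start = orfs$start, end = orfs$end, strand = orfs$strand,
    labels = purrr::pmap_chr(res, function(C, L, T) {
      paste(c("C", "L", "T")[c(C, L, T)], collapse = ",")
    }),
    C = res$C, L = res$L, T = res$T
  )
}

# The window bp strictly upstream of the start codon, in coding-strand
# orientation. The ATG itself is excluded.
upstream_window <- function(genome, start, end, strand, window) {
  len <- genome_length(genome)
  if (strand == "+") {
    lo <- start - window
    hi <- start - 1L
    if (!genome$circular && lo < 1L) {
      warning("upstream window truncated at linear genome start")
      lo <- 1L
    }
    if (hi < lo) return("")
    if (genome$circular) {
      extract_span(genome$seq, wrap_pos(lo, len),
                   wrap_pos(lo, len) + (hi - lo), circular = TRUE)
    } else {
      substr(genome$seq, lo, hi)
    }
  } else {
    # start codon's first base sits at `end` on the forward strand
    lo <- end + 1L
    hi <- end + window
    if (!genome$circular && hi > len) {
      warning("upstream window truncated at linear genome end")
      hi <- len
    }
    if (hi < lo) return("")
    revcomp(extract_span(genome$seq, lo, hi, circular = genome$circular))
  }
}
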