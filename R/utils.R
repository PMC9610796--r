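# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @importFrom stats setNames
COMPLEMENT <- setNames(
  c("T", "G", "C", "A", "N"),
  c("A", "C", "G", "T", "N")
)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' @param x A nucleotide string over A/C/G/T/N (uppercase).
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chars_seq(rev(unname(COMPLEMENT[seq_chars(x)])))
}

# Vectorized reverse complement for character vectors of equal importance.
revcomp_vec <- function(x) vapply(x, revcomp, character(1), USE.NAMES = FALSE)

# Translate a vector of codon strings with the standard genetic code
# (translation table 1). Stop codons give "*"; codons containing N give "X".
codons_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

translate_nt <- function(nt) {
  n <- nchar(nt)
  stopifnot(n %% 3 == 0)
  starts <- seq(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  paste(codons_to_aa(codons), collapse = "")
}

# Wrap a 1-based position onto 1..len (circular arithmetic).
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

# Extract a subsequence by 1-based inclusive coordinates; end may exceed the
# sequence length for circular genomes, in which case the extraction wraps.
extract_span <- function(seq, start, end, circular = FALSE) {
  len <- nchar(seq)
  if (end <= len && start >= 1L) {
    return(substr(seq, start, end))
  }
  if (!circular) {
    stop("coordinates outside linear sequence", call. = FALSE)
  }
  idx <- wrap_pos(seq(start, end), len)
  chars_seq(seq_chars(seq)[idx])
}

# Length in bp of the overlap between two intervals on a circle of size `len`.
# Intervals are given as (start, end) with end possibly > len (wrapped
# representation). On linear genomes pass len = NULL.
interval_overlap <- function(s1, e1, s2, e2, len = NULL) {
  segs <- function(s, e) {
    if (is.null(len) || e <= len) {
      list(c(s, e))
    } else {
      list(c(s, len), c(1L, e - len))
    }
  }
  ov <- 0L
  for (a in segs(s1, e1)) {
    for (b in segs(s2, e2)) {
      lo <- max(a[1], b[1])
      hi <- min(a[2], b[2])
      if (hi >= lo) ov <- ov + (hi - lo + 1L)
    }
  }
  ov
}

# Is interval (s1, e1) fully contained in (s2, e2)? Wrapped representation.
interval_contained <- function(s1, e1, s2, e2, len = NULL) {
  span1 <- e1 - s1 + 1L
  interval_overlap(s1, e1, s2, e2, len) == span1
}

abort_npv <- function(msg, class) {
  rlang::abort(msg, class = paste0("npvanno_error_", class))
}
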