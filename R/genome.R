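#' Construct a genome object
#'
#' A genome is a nucleotide sequence with an identifier and a topology flag.
#' All coordinates used by the annotation functions are 1-based inclusive; on
#' circular genomes coordinate arithmetic wraps modulo the sequence length.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide string over A/C/G/T/N. Lowercase input is
#'   upper-cased; U is mapped to T.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `npv_genome`: a list with elements `id`, `seq`
#'   and `circular`.
#' @examples
#' g <- genome("g1", "acgtACGT", circular = TRUE)
#' genome_length(g)
#' @export
genome <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (nchar(seq) == 0L) {
    abort_npv("genome sequence is empty", "empty_sequence")
  }
  bad <- unique(seq_chars(gsub("[ACGTN]", "", seq)))
  if (length(bad) > 0L) {
    abort_npv(
      paste0("illegal character(s) in sequence: ", paste(bad, collapse = ", ")),
      "illegal_character"
    )
  }
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular)),
    class = "npv_genome"
  )
}

#' @export
print.npv_genome <- function(x, ...) {
  cat(sprintf(
    "<npv_genome> %s: %s bp, %s\n", x$id,
    format(nchar(x$seq), big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Genome length in bp
#' @param genome An `npv_genome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' Read genomes from a FASTA file
#'
#' Sequences are upper-cased, U is mapped to T, and any character outside
#' A/C/G/T/N is rejected. Duplicate record identifiers and empty files are
#' errors.
#'
#' @param path Path to a (multi-)FASTA file.
#' @param circular Logical, recycled over records: topology flag to attach.
#' @return A list of [genome()] objects.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) {
    abort_npv(paste0("input not found: ", path), "input_not_found")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_npv(paste0("FASTA parse failure: ", conditionMessage(e)), "parse")
  )
  if (length(set) == 0L) {
    abort_npv("empty FASTA file", "empty_file")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort_npv("duplicate sequence ids in FASTA", "duplicate_ids")
  }
  circular <- rep_len(circular, length(set))
  purrr::map2(
    ids, seq_along(ids),
    function(id, i) genome(id, as.character(set[[i]]), circular = circular[i])
  )
}

#' Write genomes to a FASTA file
#'
#' @param genomes A [genome()] object or list of them.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "npv_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(seqs) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' GC content of a genome
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator.
#'
#' @param genome An `npv_genome`, or a plain nucleotide string.
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content(genome("g", "ACGT")) # 0.5
#' @export
gc_content <- function(genome) {
  seq <- if (inherits(genome, "npv_genome")) genome$seq else toupper(genome)
  counts <- table(factor(seq_chars(seq), levels = c(DNA_BASES, "N")))
  denom <- sum(counts[DNA_BASES])
  if (denom == 0L) {
    abort_npv("sequence contains no unambiguous bases", "all_ambiguous")
  }
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' GC content as a display percentage
#'
#' Percentage rounded half-up to 2 decimals (the convention used when
#' reporting genome statistics).
#' @param genome An `npv_genome` or nucleotide string.
#' @return Numeric percentage, e.g. `34.17`.
#' @export
gc_percent <- function(genome) {
  x <- gc_content(genome) * 100
  # round half-up at 2 decimals (base round() is banker's rounding)
  floor(x * 100 + 0.5) / 100
}

#' Rotate a circular genome to a new origin
#'
#' Re-linearizes a circular genome so that the base at `new_origin` becomes
#' position 1 — the convention used to place the first nucleotide of the
#' polyhedrin (polh) ORF at position 1 in alphabaculovirus genome records.
#'
#' @param genome A circular `npv_genome`.
#' @param new_origin 1-based coordinate that becomes position 1.
#' @return The rotated `npv_genome`, with an attribute `coord_map`: a
#'   function mapping old 1-based coordinates to new coordinates (a bijection
#'   on `1..length`).
#' @examples
#' g <- genome("g", "AACGTT", circular = TRUE)
#' rotate_to_origin(g, 3)$seq # "CGTTAA"
#' @export
rotate_to_origin <- function(genome, new_origin) {
  if (!genome$circular) {
    abort_npv("cannot rotate linear sequence", "linear_rotation")
  }
  len <- genome_length(genome)
  if (new_origin < 1L || new_origin > len) {
    abort_npv("new_origin outside genome", "bad_origin")
  }
  rotated <- if (new_origin == 1L) {
    genome$seq
  } else {
    paste0(
      substr(genome$seq, new_origin, len),
      substr(genome$seq, 1L, new_origin - 1L)
    )
  }
  out <- genome(genome$id, rotated, circular = TRUE)
  attr(out, "coord_map") <- function(pos) wrap_pos(pos - new_origin + 1L, len)
  out
}

#' Coordinate map of a rotated genome
#' @param genome The result of [rotate_to_origin()].
#' @return The old-to-new coordinate mapping function.
#' @export
coord_map <- function(genome) {
  f <- attr(genome, "coord_map")
  if (is.null(f)) function(pos) pos else f
}
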