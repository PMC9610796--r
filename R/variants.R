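VARIANT_CLASSES <- c(
  "hr_or_intergenic", "synonymous", "nonsynonymous",
  "inframe_indel", "frameshift_indel"
)

#' Read a variant table
#'
#' Expects a TSV with columns `position`, `ref`, `alt`, `frequency`
#' (frequency as a fraction in `[0, 1]`). SNPs have single-base ref and alt;
#' indels have alleles of unequal length anchored on their first (unchanged)
#' base, VCF-style, left-aligned.
#'
#' @param path Path to the TSV.
#' @return A tibble of variants.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) {
    abort_npv(paste0("input not found: ", path), "input_not_found")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt", "frequency")
  if (!all(need %in% names(df))) {
    abort_npv("variant table needs columns position, ref, alt, frequency", "parse")
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(position = as.integer(.data$position),
                  ref = toupper(.data$ref), alt = toupper(.data$alt),
                  frequency = as.numeric(.data$frequency))
}

#' Filter variants by minimum frequency
#'
#' Retains variants whose frequency is strictly greater than `min_freq`
#' (the `> 10%` convention used when reporting intra-isolate variation).
#'
#' @param variants Variant tibble.
#' @param min_freq Exclusive lower bound (default 0.10).
#' @return The filtered tibble.
#' @export
filter_variants <- function(variants, min_freq = 0.10) {
  if (any(variants$frequency < 0 | variants$frequency > 1)) {
    abort_npv("frequencies must lie in [0, 1]", "bad_frequency")
  }
  dplyr::filter(variants, .data$frequency > min_freq)
}

#' Classify variants against an annotation
#'
#' Assigns each variant one of five classes. A variant falling in an hr, or
#' in no annotated ORF, is `hr_or_intergenic` (hr takes precedence over any
#' overlapping ORF). A SNP inside an annotated ORF is translated strand-aware
#' in its codon context: `synonymous` iff the amino acid is unchanged, else
#' `nonsynonymous`. An indel inside an ORF is `inframe_indel` iff the allele
#' length difference is a multiple of 3, else `frameshift_indel`. A position
#' covered by two overlapping ORFs is classified against the longer ORF, with
#' a warning.
#'
#' @param variants Variant tibble (`position`, `ref`, `alt`, `frequency`).
#' @param genome The [genome()].
#' @param orfs Annotated ORF tibble.
#' @param hrs hr tibble from [classify_hrs()] (or any tibble with
#'   `region_start`/`region_end`); may be `NULL`.
#' @return The input tibble with a `class` column added.
#' @export
classify_variants <- function(variants, genome, orfs, hrs = NULL) {
  len <- if (genome$circular) genome_length(genome) else NULL
  cls <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    classify_one_variant(
      variants$position[i], variants$ref[i], variants$alt[i],
      genome, orfs, hrs, len
    )
  })
  dplyr::mutate(variants, class = cls)
}

classify_one_variant <- function(pos, ref, alt, genome, orfs, hrs, len) {
  glen <- genome_length(genome)
  if (pos < 1L || pos > glen) {
    abort_npv("variant position outside genome", "bad_position")
  }
  is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
  # changed-base footprint: the anchored indel representation leaves the
  # first base unchanged
  foot_lo <- if (is_snp) pos else pos + 1L
  foot_hi <- pos + max(nchar(ref) - 1L, if (is_snp) 0L else 1L)
  in_hr <- !is.null(hrs) && nrow(hrs) > 0L &&
    any(vapply(seq_len(nrow(hrs)), function(j) {
      interval_overlap(foot_lo, foot_hi,
                       hrs$region_start[j], hrs$region_end[j], len) > 0L
    }, logical(1)))
  if (in_hr) return("hr_or_intergenic")
  hit <- which(vapply(seq_len(nrow(orfs)), function(j) {
    interval_overlap(foot_lo, foot_hi, orfs$start[j], orfs$end[j], len) > 0L
  }, logical(1)))
  if (length(hit) == 0L) return("hr_or_intergenic")
  if (length(hit) > 1L) {
    warning("variant position in overlapping ORFs; classifying against the longest")
    hit <- hit[which.max(orfs$aa_length[hit])]
  }
  orf <- orfs[hit, ]
  if (!is_snp) {
    diff <- abs(nchar(ref) - nchar(alt))
    return(if (diff %% 3L == 0L) "inframe_indel" else "frameshift_indel")
  }
  # strand-aware codon comparison
  nt <- orf_nt(orf, genome)
  offset <- if (orf$strand == "+") {
    circular_offset(pos, orf$start, glen, genome$circular)
  } else {
    (orf$end - orf$start) - circular_offset(pos, orf$start, glen, genome$circular)
  }
  codon_i <- offset %/% 3L
  within <- offset %% 3L
  codon <- substr(nt, codon_i * 3L + 1L, codon_i * 3L + 3L)
  base_alt <- if (orf$strand == "+") alt else unname(COMPLEMENT[alt])
  base_ref <- if (orf$strand == "+") ref else unname(COMPLEMENT[ref])
  if (substr(codon, within + 1L, within + 1L) != base_ref) {
    warning("reference allele does not match the genome sequence")
  }
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- base_alt
  if (codons_to_aa(codon) == codons_to_aa(alt_codon)) "synonymous" else "nonsynonymous"
}

# 0-based offset of pos from start, walking forward with circular wrap.
circular_offset <- function(pos, start, glen, circular) {
  off <- pos - start
  if (off < 0L && circular) off <- off + glen
  off
}

#' Summarize variant classes
#'
#' @param variants Classified variant tibble (with `class`).
#' @return A tibble with one row per class (all five classes always present)
#'   and column `n`; counts sum to `nrow(variants)`.
#' @export
summarize_variants <- function(variants) {
  counts <- table(factor(variants$class, levels = VARIANT_CLASSES))
  tibble::tibble(class = VARIANT_CLASSES, n = as.integer(counts))
}
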