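#' Construct an ORF record
#'
#' Coordinates are 1-based inclusive on the forward strand; reverse-strand
#' ORFs keep `start < end` with `strand = "-"`. ORFs spanning the circular
#' junction are represented with `end > genome length` (the GFF3 writer splits
#' them into two segments). The span must be a positive multiple of 3 and the
#' amino-acid length is `span/3 - 1` (stop codon excluded).
#'
#' @param start,end 1-based inclusive coordinates of the first base of the
#'   start codon and last base of the stop codon (forward-strand projection).
#' @param strand `"+"` or `"-"`.
#' @param orf_id Integer id (assigned by [renumber_orfs()]).
#' @param name Gene name, if known.
#' @param annotation_basis One of `core_gene`, `alphabaculovirus_conserved`,
#'   `homolog`, `ab_initio`.
#' @return A one-row tibble with class `npv_orfs`.
#' @examples
#' orf_record(11799, 12035, "-") # 78 amino acids
#' @export
orf_record <- function(start, end, strand = "+", orf_id = NA_integer_,
                       name = NA_character_,
                       annotation_basis = NA_character_) {
  span <- end - start + 1L
  if (span <= 0L || span %% 3L != 0L) {
    abort_npv("ORF span must be a positive multiple of 3", "bad_span")
  }
  if (!strand %in% c("+", "-")) abort_npv("strand must be + or -", "bad_strand")
  out <- tibble::tibble(
    orf_id = as.integer(orf_id),
    name = name,
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    aa_length = as.integer(span / 3L - 1L),
    annotation_basis = annotation_basis
  )
  class(out) <- c("npv_orfs", class(out))
  out
}

as_orf_tbl <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- unique(c("npv_orfs", class(out)))
  out
}

#' Find open reading frames in all six frames
#'
#' Reports every maximal ATG-to-stop ORF on both strands with at least
#' `min_codons` codons (start codon counted, stop codon excluded). Only the
#' longest ORF per stop codon and frame is reported, i.e. nested in-frame
#' ORFs from internal ATGs are suppressed. On circular genomes reading frames
#' continue across the junction; junction-spanning ORFs are reported with
#' `end > genome length` and each ORF is reported exactly once.
#'
#' @param genome An [genome()] object.
#' @param min_codons Minimum number of codons (default 50, the conventional
#'   annotation floor for baculovirus genomes).
#' @return A tibble of ORF records sorted by start coordinate, with
#'   `annotation_basis = NA` (assigned later by [annotate_orfs()]).
#' @export
find_orfs <- function(genome, min_codons = 50L) {
  len <- genome_length(genome)
  fwd <- scan_strand_orfs(genome$seq, genome$circular, min_codons)
  rev <- scan_strand_orfs(revcomp(genome$seq), genome$circular, min_codons)
  out <- dplyr::bind_rows(
    dplyr::mutate(fwd, strand = "+"),
    # map reverse-scan coordinates back to the forward strand; wrapped
    # reverse ORFs (end > len on the revcomp) wrap on the forward strand too
    dplyr::mutate(rev,
      new_start = wrap_pos(len - .data$end + 1L, len),
      new_end = .data$new_start + (.data$end - .data$start),
      start = .data$new_start, end = .data$new_end,
      new_start = NULL, new_end = NULL, strand = "-"
    )
  )
  if (nrow(out) == 0L) {
    return(as_orf_tbl(orf_record(1, 3)[0, ]))
  }
  out <- dplyr::distinct(out, .data$start, .data$end, .data$strand)
  out <- dplyr::arrange(out, .data$start, .data$end, .data$strand)
  as_orf_tbl(tibble::tibble(
    orf_id = NA_integer_, name = NA_character_,
    start = as.integer(out$start), end = as.integer(out$end),
    strand = out$strand,
    aa_length = as.integer((out$end - out$start + 1L) / 3L - 1L),
    annotation_basis = NA_character_
  ))
}

# One-strand scan. Returns start/end in the scanned sequence's own
# coordinates, end possibly > len for junction-spanning ORFs on circular
# sequences. Maximality: first ATG after the previous in-frame stop.
scan_strand_orfs <- function(seq, circular, min_codons) {
  len <- nchar(seq)
  scan_seq <- if (circular) paste0(seq, seq) else seq
  n <- nchar(scan_seq)
  ch <- seq_chars(scan_seq)
  res <- list()
  for (f in 0:2) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(pos) == 0L) next
    codons <- paste0(ch[pos], ch[pos + 1L], ch[pos + 2L])
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons == "ATG"
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    if (length(stop_idx) == 0L || length(start_idx) == 0L) next
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    # first start codon strictly after the previous stop and before this stop
    k <- findInterval(prev_stop, start_idx) + 1L
    ok <- k <= length(start_idx)
    first_start <- rep(NA_integer_, length(stop_idx))
    first_start[ok] <- start_idx[k[ok]]
    ok <- ok & !is.na(first_start) & first_start < stop_idx
    if (!any(ok)) next
    sc <- first_start[ok]
    st <- stop_idx[ok]
    n_codons <- st - sc # codon count incl. start, excl. stop
    keep <- n_codons >= min_codons
    sc <- sc[keep]; st <- st[keep]
    if (length(sc) == 0L) next
    start_bp <- pos[sc]
    end_bp <- pos[st] + 2L
    if (circular) {
      keep2 <- start_bp <= len & (end_bp - start_bp + 1L) <= len
      start_bp <- start_bp[keep2]; end_bp <- end_bp[keep2]
    }
    if (length(start_bp)) {
      res[[length(res) + 1L]] <- tibble::tibble(start = start_bp, end = end_bp)
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  if (circular) {
    # one report per canonical stop codon (its position mod len identifies
    # the circular frame): keep the longest
    out$stop_mod <- wrap_pos(out$end, len)
    out <- out |>
      dplyr::group_by(.data$stop_mod) |>
      dplyr::slice_max(.data$end - .data$start, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("start", "end")
  }
  out
}

#' Translate an ORF to its amino-acid sequence
#'
#' Uses the standard genetic code (translation table 1). The stop codon is
#' excluded from the returned peptide. An internal stop codon is an error.
#'
#' @param orf A one-row ORF tibble (or a row of one).
#' @param genome The [genome()] the coordinates refer to.
#' @return Amino-acid string of length `aa_length`.
#' @export
translate_orf <- function(orf, genome) {
  nt <- orf_nt(orf, genome)
  aa <- translate_nt(nt)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", body, fixed = TRUE)) {
    abort_npv("ORF interrupted: internal stop codon", "internal_stop")
  }
  if (substr(aa, nchar(aa), nchar(aa)) != "*") {
    abort_npv("ORF does not end in a stop codon", "no_stop")
  }
  body
}

# Coding-strand nucleotide sequence of an ORF (start codon .. stop codon).
orf_nt <- function(orf, genome) {
  nt <- extract_span(genome$seq, orf$start, orf$end, genome$circular)
  if (orf$strand == "-") nt <- revcomp(nt)
  nt
}

# Average residue masses (Da), standard values for unmodified residues.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water, in daltons.
#'
#' @param aa Amino-acid string (one-letter codes, no stop).
#' @return Mass in Da.
#' @examples
#' molecular_weight("AAA") # 231.2517
#' @export
molecular_weight <- function(aa) {
  ch <- seq_chars(toupper(aa))
  bad <- setdiff(unique(ch), names(AA_AVG_MASS))
  if (length(bad)) {
    abort_npv(paste0("unknown residue(s): ", paste(bad, collapse = ", ")), "bad_residue")
  }
  sum(AA_AVG_MASS[ch]) + WATER_MASS
}

#' Molecular weight in kDa, 1 decimal
#' @param aa Amino-acid string.
#' @return kDa rounded to 1 decimal, as printed in annotation tables.
#' @export
molecular_weight_kda <- function(aa) {
  floor(molecular_weight(aa) / 1000 * 10 + 0.5) / 10
}

#' Apply annotation filter rules to called ORFs
#'
#' Implements the conventional baculovirus annotation filter: every ORF with
#' an entry in the homology table is annotated (basis `core_gene`,
#' `alphabaculovirus_conserved` or `homolog` according to the table's source
#' tag). An ORF without homology support is annotated (`ab_initio`) only if
#' (a) it is not fully contained within an hr, (b) it overlaps no hr by more
#' than `max_overlap` bp, (c) it overlaps no longer annotated ORF by more than
#' `max_overlap` bp (equal-length conflicts are resolved toward the ORF with
#' the earlier start coordinate), and (d) `coding_predicate` returns `TRUE`
#' for it.
#'
#' Overlaps are measured in bp on the forward-strand projection regardless of
#' strand, with circular wrap-around.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param genome The genome (for circular overlap arithmetic).
#' @param hrs Optional hr tibble (needs `region_start`, `region_end` columns),
#'   e.g. from [classify_hrs()]; may be `NULL` or empty.
#' @param homology Optional homology table with columns `orf_key`
#'   (`"start:end:strand"`), `homolog_name`, `source_tag`
#'   (`core` / `alpha_conserved` / `other`); stands in for protein-similarity
#'   search results. May be `NULL`.
#' @param coding_predicate Function `(orf_row, genome) -> logical(1)`;
#'   pluggable stand-in for agreement between two ab initio gene predictors.
#'   Default: codon-usage similarity to the homology-supported ORF set, see
#'   [make_codon_usage_predicate()].
#' @param max_overlap Maximum tolerated overlap in bp (default 75).
#' @return The annotated subset of `orfs` with `annotation_basis` and `name`
#'   filled in, sorted by start coordinate.
#' @export
annotate_orfs <- function(orfs, genome, hrs = NULL, homology = NULL,
                          coding_predicate = NULL, max_overlap = 75L) {
  len <- if (genome$circular) genome_length(genome) else NULL
  orfs <- tibble::as_tibble(orfs)
  key <- paste(orfs$start, orfs$end, orfs$strand, sep = ":")
  basis_map <- c(
    core = "core_gene", alpha_conserved = "alphabaculovirus_conserved",
    other = "homolog"
  )
  if (!is.null(homology) && nrow(homology) > 0L) {
    m <- match(key, homology$orf_key)
    orfs$annotation_basis <- ifelse(
      is.na(m), NA_character_, unname(basis_map[homology$source_tag[m]])
    )
    orfs$name <- ifelse(is.na(m), orfs$name, homology$homolog_name[m])
  } else {
    orfs$annotation_basis <- NA_character_
  }
  kept <- orfs[!is.na(orfs$annotation_basis), , drop = FALSE]
  cand <- orfs[is.na(orfs$annotation_basis), , drop = FALSE]
  if (nrow(cand) > 0L) {
    if (is.null(coding_predicate)) {
      coding_predicate <- make_codon_usage_predicate(kept, genome)
    }
    # longest first; ties toward earlier start so the tie-break is
    # "first kept wins"
    cand <- dplyr::arrange(cand, dplyr::desc(.data$aa_length), .data$start)
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      ok <- TRUE
      if (!is.null(hrs) && nrow(hrs) > 0L) {
        for (j in seq_len(nrow(hrs))) {
          if (interval_contained(row$start, row$end,
                                 hrs$region_start[j], hrs$region_end[j], len)) {
            ok <- FALSE; break
          }
          if (interval_overlap(row$start, row$end,
                               hrs$region_start[j], hrs$region_end[j], len) >
              max_overlap) {
            ok <- FALSE; break
          }
        }
      }
      if (ok && nrow(kept) > 0L) {
        for (j in seq_len(nrow(kept))) {
          # strictly longer ORFs block; equal length blocks only between two
          # ab initio candidates (the earlier-start one, kept first, wins)
          longer <- kept$aa_length[j] > row$aa_length ||
            (kept$aa_length[j] == row$aa_length &&
               identical(kept$annotation_basis[j], "ab_initio"))
          if (longer &&
              interval_overlap(row$start, row$end,
                               kept$start[j], kept$end[j], len) > max_overlap) {
            ok <- FALSE; break
          }
        }
      }
      if (ok && !isTRUE(coding_predicate(row, genome))) ok <- FALSE
      if (ok) {
        row$annotation_basis <- "ab_initio"
        kept <- dplyr::bind_rows(kept, row)
      }
    }
  }
  as_orf_tbl(dplyr::arrange(kept, .data$start, .data$end))
}

#' Default coding predicate: codon-usage similarity
#'
#' Builds a predicate that accepts an ORF when the cosine similarity between
#' its relative synonymous codon usage (RSCU) vector and the mean RSCU of the
#' homology-supported ORF set exceeds `threshold`. A pluggable stand-in for
#' requiring agreement between two ab initio coding-sequence predictors.
#'
#' @param reference_orfs ORF tibble used to build the reference codon-usage
#'   profile (typically the homology-supported ORFs).
#' @param genome The genome.
#' @param threshold Cosine-similarity acceptance threshold (default 0.5).
#' @return A function `(orf_row, genome) -> logical(1)`. If `reference_orfs`
#'   is empty the predicate accepts everything.
#' @export
make_codon_usage_predicate <- function(reference_orfs, genome, threshold = 0.5) {
  if (is.null(reference_orfs) || nrow(reference_orfs) == 0L) {
    return(function(orf_row, genome) TRUE)
  }
  ref <- rowMeans(vapply(
    seq_len(nrow(reference_orfs)),
    function(i) rscu_vector(orf_nt(reference_orfs[i, ], genome)),
    numeric(64)
  ))
  function(orf_row, genome) {
    v <- rscu_vector(orf_nt(orf_row, genome))
    sim <- sum(v * ref) / sqrt(sum(v^2) * sum(ref^2))
    isTRUE(sim > threshold)
  }
}

# Relative synonymous codon usage as a fixed-order length-64 vector.
rscu_vector <- function(nt) {
  all_codons <- sort(names(Biostrings::GENETIC_CODE))
  starts <- seq(1L, nchar(nt) - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  counts <- table(factor(codons, levels = all_codons))
  aa <- Biostrings::GENETIC_CODE[all_codons]
  fam_mean <- stats::ave(as.numeric(counts), aa, FUN = mean)
  rscu <- ifelse(fam_mean > 0, as.numeric(counts) / fam_mean, 0)
  stats::setNames(rscu, all_codons)
}

#' Renumber annotated ORFs along the genome
#'
#' Assigns `orf_id` 1..N in order of start coordinate. By convention the
#' genome has been rotated so that polh starts at position 1, making polh
#' ORF 1.
#'
#' @param orfs ORF tibble.
#' @return The tibble with `orf_id` assigned, sorted by start.
#' @export
renumber_orfs <- function(orfs) {
  if (anyDuplicated(orfs$start)) {
    abort_npv("two ORFs share a start coordinate", "duplicate_start")
  }
  orfs <- dplyr::arrange(tibble::as_tibble(orfs), .data$start)
  orfs$orf_id <- seq_len(nrow(orfs))
  as_orf_tbl(orfs)
}
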