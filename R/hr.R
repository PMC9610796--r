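#' Find clusters of near-identical tandem repeats
#'
#' Detects candidate homologous regions (hrs): clusters of two or more repeat
#' units of similar length whose sequences are near-identical, allowing units
#' in reverse-complement orientation. The detector seeds with exact k-mer
#' matches (forward and reverse-complement) at unit-scale spacing, merges
#' nearby seeds into candidate regions, estimates the unit length by
#' minimizing edit distance between the first two putative units, and then
#' tiles units across the region by edit-distance matching against the first
#' unit, allowing small length jitter and either orientation.
#'
#' @param genome An [genome()] object. On circular genomes, detection wraps
#'   across the junction (regions may be reported with `region_end` greater
#'   than the genome length).
#' @param unit_min,unit_max Unit length search window in bp (default 40-80,
#'   centered on the 59-bp units typical of alphabaculovirus hrs).
#' @param min_units Minimum units per cluster (default 2).
#' @param max_unit_divergence Maximum edit distance between a unit and the
#'   cluster consensus, as a fraction of unit length (default 0.25).
#' @param gap Maximum spacing in bp between adjacent units of one region
#'   (default 250).
#' @param k Seed k-mer length (default 12).
#' @param unit_prior Unit-length prior in bp (default 59, the typical
#'   alphabaculovirus repeat unit). Always tried as a period candidate in
#'   addition to the data-derived candidates; set outside
#'   `[unit_min, unit_max]` to disable.
#' @return A tibble with one row per cluster: `cluster_id`, `region_start`,
#'   `region_end`, `n_units`, `unit_length`, `consensus`, and a list-column
#'   `units` of per-unit tibbles (`start`, `end`, `orientation`, `seq`).
#' @export
find_tandem_repeats <- function(genome, unit_min = 40L, unit_max = 80L,
                                min_units = 2L, max_unit_divergence = 0.25,
                                gap = 250L, k = 12L, unit_prior = 59L) {
  len <- genome_length(genome)
  S <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  seeds <- repeat_seeds(S, len, k, unit_min, unit_max, gap,
                        circular = genome$circular)
  empty <- tibble::tibble(
    cluster_id = integer(), region_start = integer(), region_end = integer(),
    n_units = integer(), unit_length = integer(), consensus = character(),
    units = list()
  )
  if (nrow(seeds) == 0L) return(empty)
  seeds <- assign_seed_regions(seeds, gap)
  clusters <- list()
  for (r in unique(seeds$region)) {
    rs <- seeds[seeds$region == r, ]
    # a merged seed region can chain across several distinct repeat arrays:
    # peel off clusters until no further one resolves
    claimed <- list()
    for (round in 1:10) {
      if (nrow(rs) == 0L) break
      cl <- resolve_cluster(
        S, len, rs,
        unit_min, unit_max, min_units, max_unit_divergence,
        circular = genome$circular, claimed = claimed,
        unit_prior = unit_prior
      )
      if (is.null(cl)) break
      clusters[[length(clusters) + 1L]] <- cl
      claimed[[length(claimed) + 1L]] <- c(cl$region_start, cl$region_end)
      rs <- rs[rs$hi < cl$region_start | rs$lo > cl$region_end, , drop = FALSE]
    }
  }
  if (length(clusters) == 0L) return(empty)
  out <- dplyr::bind_rows(clusters)
  # canonicalize circular duplicates (same region found in both copies)
  if (genome$circular) {
    out$canon <- wrap_pos(out$region_start, len)
    out <- out |>
      dplyr::mutate(region_start = .data$canon,
                    region_end = .data$canon +
                      (.data$region_end - .data$region_start)) |>
      dplyr::distinct(.data$canon, .keep_all = TRUE) |>
      dplyr::select(-"canon")
    # re-derive unit coordinates in canonical frame
    out$units <- purrr::map2(out$units, out$region_start, function(u, rs) {
      shift <- rs - u$start[1]
      u$start <- u$start + shift
      u$end <- u$end + shift
      u
    })
  }
  out <- dplyr::arrange(out, .data$region_start)
  # safety net: drop any cluster largely overlapping an already-kept one
  # (rotated re-detections of the same array)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ov <- interval_overlap(out$region_start[i], out$region_end[i],
                             out$region_start[j], out$region_end[j],
                             if (genome$circular) len else NULL)
      shorter <- min(out$region_end[i] - out$region_start[i],
                     out$region_end[j] - out$region_start[j]) + 1L
      if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  out
}

# Exact k-mer seed pairs at unit-scale spacing; returns intervals (lo, hi).
repeat_seeds <- function(S, len, k, unit_min, unit_max, gap, circular) {
  n <- nchar(S)
  n_kmer_start <- if (circular) len else n - k + 1L
  if (n_kmer_start < 1L || n < k) {
    return(tibble::tibble(lo = integer(), hi = integer()))
  }
  # all start positions needed: starts in copy 1, partners may lie in copy 2
  all_starts <- seq_len(min(n - k + 1L, if (circular) len + 2L * unit_max + gap else n))
  kmers <- substring(S, all_starts, all_starts + k - 1L)
  d_lo <- max(4L, floor(unit_min * 0.8))
  d_hi <- 2L * unit_max + gap
  groups <- split(all_starts, kmers)
  pair_lo <- integer(); pair_hi <- integer()
  add_pairs <- function(pos_i, pos_j) {
    # all (i, j) with j - i in [d_lo, d_hi]
    for (i in pos_i) {
      js <- pos_j[pos_j - i >= d_lo & pos_j - i <= d_hi]
      if (length(js)) {
        pair_lo <<- c(pair_lo, rep(i, length(js)))
        pair_hi <<- c(pair_hi, js)
      }
    }
  }
  # forward-orientation matches
  for (g in groups) {
    if (length(g) >= 2L) add_pairs(g[-length(g)], g)
  }
  # reverse-complement matches
  uk <- names(groups)
  rc_uk <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uk)))
  m <- match(rc_uk, uk)
  has_rc <- which(!is.na(m) & m >= seq_along(uk)) # each unordered pair once
  for (idx in has_rc) {
    a <- groups[[idx]]; b <- groups[[m[idx]]]
    add_pairs(a, b)
    if (m[idx] != idx) add_pairs(b, a)
  }
  if (length(pair_lo) == 0L) {
    return(tibble::tibble(lo = integer(), hi = integer(), diff = integer()))
  }
  keep <- pair_lo <= (if (circular) len else n)
  tibble::tibble(lo = pair_lo[keep], hi = pair_hi[keep] + k - 1L,
                 diff = pair_hi[keep] - pair_lo[keep])
}

# Group seeds into regions: merge overlapping/nearby seed intervals.
assign_seed_regions <- function(seeds, gap) {
  seeds <- dplyr::arrange(seeds, .data$lo, .data$hi)
  region <- integer(nrow(seeds))
  cur <- 1L
  cur_hi <- seeds$hi[1]
  region[1] <- cur
  for (i in seq_len(nrow(seeds))[-1]) {
    if (seeds$lo[i] <= cur_hi + gap) {
      cur_hi <- max(cur_hi, seeds$hi[i])
    } else {
      cur <- cur + 1L
      cur_hi <- seeds$hi[i]
    }
    region[i] <- cur
  }
  seeds$region <- region
  seeds
}

modal_value <- function(x) {
  as.integer(names(sort(table(x), decreasing = TRUE))[1])
}

# Jitter-free greedy tiling at a fixed period and phase: extend left by whole
# units, then tile right while each unit stays within the divergence ceiling
# of the first tile. Tiles never enter `claimed` intervals (regions already
# resolved in an earlier peel round). Returns NULL when the phase start is
# out of range.
tile_at_phase <- function(S, s, p, max_div, n, hi, claimed = list()) {
  if (s < 1L || s + p - 1L > n) return(NULL)
  blocked <- function(lo2, hi2) {
    for (cl in claimed) if (hi2 >= cl[1] && lo2 <= cl[2]) return(TRUE)
    FALSE
  }
  if (blocked(s, s + p - 1L)) return(NULL)
  ref <- substr(S, s, s + p - 1L)
  ceiling_d <- max_div * p
  start <- s
  total_d <- 0
  while (start - p >= 1L && !blocked(start - p, start - 1L)) {
    ud <- unit_dist(substr(S, start - p, start - 1L), ref)
    if (ud$d <= ceiling_d) {
      start <- start - p
      total_d <- total_d + ud$d
    } else break
  }
  n_units <- (s - start) %/% p
  cur <- s
  repeat {
    if (cur + p - 1L > n || blocked(cur, cur + p - 1L)) break
    ud <- unit_dist(substr(S, cur, cur + p - 1L), ref)
    if (ud$d > ceiling_d) break
    total_d <- total_d + ud$d
    n_units <- n_units + 1L
    cur <- cur + p
    if (cur > hi + p) break
  }
  if (n_units == 0L) return(NULL)
  list(start = start, end = cur - 1L, n_units = n_units, total_d = total_d)
}

# Orientation-aware distance of x against ref; returns list(d, orient).
# Equal-length comparisons use Hamming distance (identical to edit distance
# for the substitution-dominated divergence the ceiling models, and much
# faster); unequal lengths fall back to full edit distance.
unit_dist <- function(x, ref) {
  if (nchar(x) == nchar(ref)) {
    xc <- strsplit(x, "", fixed = TRUE)[[1]]
    rc <- strsplit(ref, "", fixed = TRUE)[[1]]
    df <- sum(xc != rc)
    dr <- sum(rev(unname(COMPLEMENT[xc])) != rc)
  } else {
    df <- utils::adist(x, ref)[1, 1]
    dr <- utils::adist(revcomp(x), ref)[1, 1]
  }
  if (df <= dr) list(d = df, orientation = "forward") else list(d = dr, orientation = "reverse")
}

.npv_cache <- new.env(parent = emptyenv())

dna_submat <- function() {
  if (is.null(.npv_cache$submat)) {
    .npv_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE
    )
  }
  .npv_cache$submat
}

# Turn one region's seed set into a cluster of tiled units (or NULL).
resolve_cluster <- function(S, len, seeds, unit_min, unit_max, min_units,
                            max_div, circular, claimed = list(),
                            unit_prior = 59L) {
  n <- nchar(S)
  hi <- max(seeds$hi)
  # period estimate: modal seed spacing at unit scale, falling back to half
  # the modal spacing at two-unit scale (alternating-orientation regions)
  d1 <- seeds$diff[seeds$diff >= unit_min & seeds$diff <= unit_max]
  d2 <- seeds$diff[seeds$diff >= 2L * unit_min & seeds$diff <= 2L * unit_max]
  top_values <- function(x, k) {
    if (length(x) == 0L) return(integer(0))
    utils::head(as.integer(names(sort(table(x), decreasing = TRUE))), k)
  }
  # period candidates from unit-scale spacings, half the two-unit-scale
  # spacings (regions whose units alternate orientation), and the unit-length
  # prior (a lone forward/reverse unit pair yields only mirror-symmetric seed
  # spacings that never equal the period, so the prior is tried regardless)
  p0_cand <- unique(c(top_values(d1, 4L), top_values(d2, 3L) %/% 2L))
  prior_p <- unit_prior[unit_prior >= unit_min & unit_prior <= unit_max]
  # the prior is redundant when a data-derived candidate already sits on it
  if (length(prior_p) && length(p0_cand) &&
      min(abs(p0_cand - prior_p)) <= 2L) {
    prior_p <- integer(0)
  }
  if (length(p0_cand) == 0L && length(prior_p) == 0L) return(NULL)
  # anchor candidates. "Gated" anchors pass a direct two-unit similarity
  # test at the seed position; additionally one ungated representative per
  # sub-cluster of supporting seeds is kept (covering seeds that sit deep
  # inside a unit of a short region), but ungated anchors must later tile at
  # much tighter divergence so low-complexity junk cannot sneak through.
  anchors <- list()
  for (p0 in unique(c(p0_cand, prior_p))) {
    support <- abs(seeds$diff - p0) <= 2L | abs(seeds$diff - 2L * p0) <= 4L
    if (p0 %in% prior_p) support <- rep(TRUE, nrow(seeds))
    lows <- sort(unique(seeds$lo[support]))
    if (length(lows) == 0L) next
    p_cand <- max(unit_min, p0 - 3L):min(unit_max, p0 + 3L)
    n_gated <- 0L
    for (cand in lows) {
      if (cand + 2L * max(p_cand) - 1L > n || n_gated >= 2L) break
      score <- vapply(p_cand, function(pp) {
        u1 <- substr(S, cand, cand + pp - 1L)
        u2 <- substr(S, cand + pp, cand + 2L * pp - 1L)
        unit_dist(u2, u1)$d / pp
      }, numeric(1))
      if (min(score) <= max_div) {
        anchors[[length(anchors) + 1L]] <- list(
          lo = cand, p = p_cand[which.min(score)], gated = TRUE
        )
        n_gated <- n_gated + 1L
      }
    }
    grp_starts <- lows[c(TRUE, diff(lows) > 2L * p0)]
    n_ungated <- if (p0 %in% prior_p) 5L else 10L
    for (cand in utils::head(grp_starts, n_ungated)) {
      anchors[[length(anchors) + 1L]] <- list(lo = cand, p = p0, gated = FALSE)
    }
  }
  if (length(anchors) == 0L) return(NULL)
  if (length(anchors) > 24L) {
    gated_first <- order(!vapply(anchors, `[[`, logical(1), "gated"))
    anchors <- anchors[gated_first[1:24]]
  }
  # resolve unit boundaries and the tandem-rotation ambiguity: over every
  # candidate anchor, nearby period, and tiling phase, keep the tiling that
  # maximizes covered bases penalized by twice the accumulated edit distance;
  # only at the true unit boundaries do the edge tiles avoid paying for
  # flanking non-repeat sequence
  best <- NULL
  for (a in anchors) {
    for (pp in max(unit_min, a$p - 1L):min(unit_max, a$p + 1L)) {
      for (delta in (-3L):(pp - 1L)) {
        t0 <- tile_at_phase(S, a$lo - delta, pp, max_div, n, hi, claimed)
        if (is.null(t0) || t0$n_units < min_units) next
        if (!a$gated && t0$total_d / t0$n_units > max_div * pp / 2) next
        cover <- t0$end - t0$start + 1L
        sc <- cover - 2 * t0$total_d
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && t0$start < best$start)) {
          best <- list(start = t0$start, p = pp, sc = sc,
                       total_d = t0$total_d)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  start <- best$start
  p <- best$p
  ref <- substr(S, start, start + p - 1L)
  ceiling_d <- max_div * p
  # final tiling with +-3 bp length jitter
  units <- list()
  cur <- start
  repeat {
    best_d <- Inf; best_len <- NA_integer_; best_or <- "forward"
    for (dl in -3L:3L) {
      L_u <- p + dl
      if (L_u < unit_min - 3L || cur + L_u - 1L > n) next
      cand <- substr(S, cur, cur + L_u - 1L)
      ud <- unit_dist(cand, ref)
      if (ud$d < best_d) {
        best_d <- ud$d; best_len <- L_u; best_or <- ud$orientation
      }
    }
    if (!is.finite(best_d) || best_d > ceiling_d) break
    units[[length(units) + 1L]] <- tibble::tibble(
      start = cur, end = cur + best_len - 1L, orientation = best_or,
      seq = substr(S, cur, cur + best_len - 1L)
    )
    cur <- cur + best_len
    if (cur > hi + p) break # stop shortly after the seeded extent
  }
  if (length(units) < min_units) return(NULL)
  u <- dplyr::bind_rows(units)
  # consensus with one refinement pass: re-orient against the consensus
  norm <- ifelse(u$orientation == "reverse", revcomp_vec(u$seq), u$seq)
  cons <- build_consensus(norm)$consensus
  reor <- purrr::map(u$seq, unit_dist, ref = cons)
  u$orientation <- vapply(reor, `[[`, character(1), "orientation")
  dists <- vapply(reor, `[[`, numeric(1), "d")
  keep <- dists <= max_div * nchar(cons)
  u <- u[keep, , drop = FALSE]
  if (nrow(u) < min_units) return(NULL)
  norm <- ifelse(u$orientation == "reverse", revcomp_vec(u$seq), u$seq)
  cons <- build_consensus(norm)$consensus
  tibble::tibble(
    cluster_id = NA_integer_,
    region_start = u$start[1], region_end = u$end[nrow(u)],
    n_units = nrow(u), unit_length = nchar(cons),
    consensus = cons, units = list(u)
  )
}

#' Build a consensus and base-frequency profile from repeat units
#'
#' Units must already be orientation-normalized (reverse units complemented).
#' Equal-length units are stacked positionally; units whose length differs
#' from the modal length are placed onto the consensus columns by global
#' pairwise alignment. The consensus takes the position-wise majority base
#' (ties broken toward the lexicographically smallest base).
#'
#' @param units Character vector of unit sequences (length >= 2 for a
#'   meaningful consensus; an empty vector is an error).
#' @return An object of class `npv_consensus`: list with `consensus` (string),
#'   `freq` (4 x L count matrix, rows A/C/G/T; each column sums to the number
#'   of units covering that position) and `n_units`.
#' @examples
#' build_consensus(c("ACGT", "ACGA", "ACGT"))$consensus # "ACGT"
#' @export
build_consensus <- function(units) {
  if (length(units) == 0L) {
    abort_npv("cannot build a consensus from zero units", "no_units")
  }
  lens <- nchar(units)
  modal_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  base_units <- units[lens == modal_len]
  mat <- do.call(rbind, strsplit(base_units, "", fixed = TRUE))
  freq <- apply(mat, 2, function(col) {
    table(factor(col, levels = DNA_BASES))
  })
  freq <- matrix(as.integer(freq), nrow = 4L,
                 dimnames = list(DNA_BASES, NULL))
  # align off-length units to the current consensus and add their votes
  off <- units[lens != modal_len]
  cons0 <- consensus_from_freq(freq)
  for (u in off) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(u), Biostrings::DNAString(cons0),
      type = "global", substitutionMatrix = dna_submat(),
      gapOpening = 4, gapExtension = 1
    )
    pat <- seq_chars(as.character(Biostrings::alignedPattern(al)))
    sub <- seq_chars(as.character(Biostrings::alignedSubject(al)))
    col <- cumsum(sub != "-") # consensus column index
    for (t in seq_along(pat)) {
      if (sub[t] != "-" && pat[t] %in% DNA_BASES) {
        freq[pat[t], col[t]] <- freq[pat[t], col[t]] + 1L
      }
    }
  }
  structure(
    list(
      consensus = consensus_from_freq(freq),
      freq = freq,
      n_units = length(units)
    ),
    class = "npv_consensus"
  )
}

consensus_from_freq <- function(freq) {
  # which.max on named counts returns the first (lexicographically smallest
  # since rows are A,C,G,T) maximum: the documented tie-break
  chars_seq(DNA_BASES[apply(freq, 2, which.max)])
}

#' @export
print.npv_consensus <- function(x, ...) {
  cat(sprintf("<npv_consensus> %d units, %d bp\n%s\n",
              x$n_units, nchar(x$consensus), x$consensus))
  invisible(x)
}

#' Tidy a consensus profile
#'
#' @param x An `npv_consensus`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `count`, `fraction`.
#' @export
tidy.npv_consensus <- function(x, ...) {
  L <- ncol(x$freq)
  tot <- colSums(x$freq)
  tibble::tibble(
    position = rep(seq_len(L), each = 4L),
    base = rep(DNA_BASES, L),
    count = as.integer(x$freq),
    fraction = as.numeric(x$freq) / rep(pmax(tot, 1L), each = 4L)
  )
}

#' Best imperfect reverse-complement palindrome in a sequence
#'
#' Scans every center (between adjacent positions) and every arm length at
#' least `min_arm`, and returns the arm maximizing the arm length subject to
#' the number of non-complementary base pairs not exceeding `max_mismatch`.
#' A position pairs with its mirror iff the two bases are reverse
#' complements. Ties go to the leftmost center.
#'
#' @param seq Nucleotide string (length >= 4).
#' @param min_arm Minimum qualifying arm length (default 3; `GAATTC` scores
#'   arm 3 with 0 mismatches).
#' @param max_mismatch Mismatch ceiling within one arm (default 0).
#' @return A list with `center` (the position left of the palindrome center:
#'   the arms span `center - arm_length + 1 .. center` and
#'   `center + 1 .. center + arm_length`), `arm_length` and `mismatches`.
#'   `arm_length` 0 when nothing qualifies.
#' @examples
#' palindrome_score("GAATTC") # center 3, arm 3, 0 mismatches
#' @export
palindrome_score <- function(seq, min_arm = 3L, max_mismatch = 0L) {
  n <- nchar(seq)
  if (n < 4L) abort_npv("sequence too short for palindrome scan", "too_short")
  ch <- seq_chars(seq)
  comp <- unname(COMPLEMENT[ch])
  best <- list(center = NA_integer_, arm_length = 0L, mismatches = NA_integer_)
  for (c0 in seq_len(n - 1L)) {
    a_max <- min(c0, n - c0)
    if (a_max < min_arm) next
    t <- seq_len(a_max)
    mism <- cumsum(ch[c0 - t + 1L] != comp[c0 + t])
    arm <- sum(mism <= max_mismatch)
    if (arm >= min_arm && arm > best$arm_length) {
      best <- list(center = c0, arm_length = arm,
                   mismatches = as.integer(mism[arm]))
    }
  }
  best
}

#' Classify repeat clusters as homologous regions
#'
#' A cluster is accepted as an hr iff its unit count is within
#' `[min_units, max_units]`, its consensus length is within
#' `[unit_min, unit_max]`, and the best imperfect palindrome of the consensus
#' (at `max_mismatch` tolerated mismatches) has arm length at least
#' `min_arm`. Accepted regions are labelled `"hr1"`, `"hr2"`, ... in genome
#' order.
#'
#' @param clusters Output of [find_tandem_repeats()].
#' @param min_units,max_units Acceptable unit counts (default 2-6, the range
#'   observed in alphabaculovirus hrs).
#' @param unit_min,unit_max Acceptable consensus length (default 40-80 bp).
#' @param min_arm Minimum palindrome arm length in the consensus (default 3).
#' @param max_mismatch Palindrome mismatch ceiling (default 2; the repeat
#'   palindromes are typically imperfect).
#' @return A tibble of hr regions: `hr_id`, `region_start`, `region_end`,
#'   `n_units`, `consensus`, `pal_center`, `pal_arm`, `pal_mismatches`, and
#'   the `units` list-column.
#' @export
classify_hrs <- function(clusters, min_units = 2L, max_units = 6L,
                         unit_min = 40L, unit_max = 80L,
                         min_arm = 3L, max_mismatch = 2L) {
  empty <- tibble::tibble(
    hr_id = character(), region_start = integer(), region_end = integer(),
    n_units = integer(), consensus = character(), pal_center = integer(),
    pal_arm = integer(), pal_mismatches = integer(), units = list()
  )
  if (nrow(clusters) == 0L) return(empty)
  pal <- purrr::map(clusters$consensus, palindrome_score,
                    min_arm = min_arm, max_mismatch = max_mismatch)
  out <- clusters |>
    dplyr::mutate(
      pal_center = purrr::map_int(pal, ~ as.integer(.x$center)),
      pal_arm = purrr::map_int(pal, ~ as.integer(.x$arm_length)),
      pal_mismatches = purrr::map_int(pal, ~ as.integer(.x$mismatches))
    ) |>
    dplyr::filter(
      .data$n_units >= min_units, .data$n_units <= max_units,
      nchar(.data$consensus) >= unit_min, nchar(.data$consensus) <= unit_max,
      .data$pal_arm >= min_arm
    )
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, .data$region_start)
  out$hr_id <- paste0("hr", seq_len(nrow(out)))
  dplyr::select(
    out, "hr_id", "region_start", "region_end", "n_units", "consensus",
    "pal_center", "pal_arm", "pal_mismatches", "units"
  )
}
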