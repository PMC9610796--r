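# The hr repeat unit used as the default seed for simulated hr cassettes:
# the 59-bp consensus of the conserved alphabaculovirus-style repeat.
HR_UNIT_59 <- "TTGAACTCGCTTTACAAGTTTAAATGTACTCGTAAAGCAAGATCAGTGGATGATGTCA"

# Guard cassette: contains stop codons in all three frames on both strands
# (TAA at offsets 2/6/10, TTA at 1/5/9) and no promoter motif (no C or G).
# It is its own reverse complement. Placed around planted features so that
# maximal ORFs never extend across feature boundaries and spurious ORFs in
# filler stay short.
GUARD <- "TTAATTAATTAA"
GUARD_LEN <- 12L

#' Default configuration for the genome simulator
#'
#' The defaults emulate an AT-rich circular alphabaculovirus-like genome:
#' ~100 kb, 34.2% GC, dozens of ORFs of 50-400 codons on both strands with
#' early/late promoter motifs planted upstream, and hrs of 2-6 copies of a
#' 59-bp palindromic unit at low per-base divergence.
#'
#' @return A named list of generator parameters.
#' @export
simulate_genome_config <- function() {
  list(
    length = 100000L,
    gc = 0.342,
    n_orfs = 80L,
    orf_codons_min = 50L,
    orf_codons_max = 400L,
    minus_strand_prob = 0.4,
    n_hrs = 6L,
    hr_units_min = 2L,
    hr_units_max = 6L,
    hr_unit = HR_UNIT_59,
    hr_mutation = 0.03,
    hr_reverse_prob = 0.25,
    promoter_window = 200L,
    promoter_probs = c(C = 0.7, L = 0.5, T = 0.25),
    homology_probs = c(core = 0.3, alpha_conserved = 0.2, other = 0.5)
  )
}

#' Simulate a genome with known annotation truth
#'
#' Assembles a circular genome from planted, non-overlapping ORF cassettes
#' (ATG..stop, codon usage biased toward the GC target, requested promoter
#' motifs planted -- and unrequested ones scrubbed -- in the upstream
#' window), hr cassettes built as mutated copies of a seed unit in mixed
#' orientations, and i.i.d. intergenic filler at the GC target. Guard
#' sequences carrying stop codons in all six frames bound every feature, so
#' planted ORFs are maximal and recovered at their exact coordinates. The
#' first ORF starts at position 1 (the polh-at-origin convention), so no
#' rotation is needed. The realized GC content is nudged onto the target by
#' complementary flips restricted to intergenic filler.
#'
#' @param config List of parameters; see [simulate_genome_config()]. Missing
#'   entries take the defaults.
#' @param seed Integer seed. One RNG stream is derived per feature class
#'   (layout, ORF contents, hr contents, promoter windows, filler) by drawing
#'   sub-seeds from the user seed, so enabling one feature class does not
#'   perturb the draws of another.
#' @return A list of class `npv_sim`: `genome` (an [genome()]), `orfs`
#'   (truth ORF tibble), `hrs` (truth hr tibble with a `units` list-column),
#'   `promoters` (truth label tibble), `homology` (homology table covering
#'   every planted ORF), `config`.
#' @export
simulate_genome <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(simulate_genome_config(), config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2L, 5L)

  # --- layout stream: strands, lengths, labels, hr placement ---------------
  set.seed(sub_seeds[1])
  n <- cfg$n_orfs
  strands <- if (n > 0L) {
    c("+", ifelse(stats::runif(max(n - 1L, 0L)) < cfg$minus_strand_prob, "-", "+"))
  } else character(0)
  n_codons <- if (n > 0L) {
    sample(seq(cfg$orf_codons_min, cfg$orf_codons_max), n, replace = TRUE)
  } else integer(0)
  labels <- purrr::map(seq_len(n), function(i) {
    p <- cfg$promoter_probs
    c("C", "L", "T")[stats::runif(3) < p[c("C", "L", "T")]]
  })
  source_tags <- if (n > 0L) {
    sample(names(cfg$homology_probs), n, replace = TRUE,
           prob = cfg$homology_probs)
  } else character(0)
  hr_slots <- if (cfg$n_hrs > 0L) {
    if (n == 0L) rep(1L, cfg$n_hrs) else {
      sort(sample(seq_len(n), cfg$n_hrs, replace = cfg$n_hrs > n))
    }
  } else integer(0)
  hr_unit_counts <- if (cfg$n_hrs > 0L) {
    sample(seq(cfg$hr_units_min, cfg$hr_units_max), cfg$n_hrs, replace = TRUE)
  } else integer(0)
  filler_lens <- pmax(stats::rpois(max(n, 1L) * 2L + cfg$n_hrs * 2L, 60L), 30L)

  # --- feature contents ----------------------------------------------------
  set.seed(sub_seeds[2])
  bodies <- purrr::map_chr(seq_len(n), function(i) {
    make_orf_cassette(n_codons[i], cfg$gc)
  })
  set.seed(sub_seeds[3])
  hr_blocks <- purrr::map(seq_len(cfg$n_hrs), function(h) {
    make_hr_cassette(cfg$hr_unit, hr_unit_counts[h], cfg$hr_mutation,
                     cfg$hr_reverse_prob)
  })
  set.seed(sub_seeds[4])
  windows <- purrr::map_chr(seq_len(n), function(i) {
    make_promoter_window(labels[[i]], cfg$promoter_window, cfg$gc)
  })

  # --- assembly ------------------------------------------------------------
  set.seed(sub_seeds[5])
  blocks <- list()       # character blocks in order
  block_mutable <- list() # logical: may GC-flips touch this block?
  orf_coord <- vector("list", n)
  hr_coord <- vector("list", cfg$n_hrs)
  fi <- 0L # filler length index
  next_filler <- function() {
    fi <<- fi + 1L
    filler_lens[((fi - 1L) %% length(filler_lens)) + 1L]
  }
  push <- function(x, mutable = FALSE) {
    blocks[[length(blocks) + 1L]] <<- x
    block_mutable[[length(block_mutable) + 1L]] <<- mutable
  }
  push_filler <- function(len) {
    parts <- compose_filler(len, cfg$gc)
    for (p in parts) push(p$seq, mutable = p$mutable)
  }
  hr_by_slot <- split(seq_len(cfg$n_hrs), hr_slots)

  if (n == 0L) {
    push_filler(next_filler())
    for (h in seq_len(cfg$n_hrs)) {
      hr_coord[[h]] <- list(block = length(blocks) + 1L)
      push(hr_blocks[[h]]$seq)
      push_filler(next_filler())
    }
  } else {
    for (i in seq_len(n)) {
      orf_coord[[i]] <- list(block = length(blocks) + 1L)
      body <- if (strands[i] == "+") bodies[i] else revcomp(bodies[i])
      push(body)
      # spacer after ORF i
      if (strands[i] == "-") push(revcomp(windows[i])) # head window of ORF i
      push_filler(next_filler())
      for (h in hr_by_slot[[as.character(i)]] %||% integer(0)) {
        hr_coord[[h]] <- list(block = length(blocks) + 1L)
        push(hr_blocks[[h]]$seq)
        push_filler(next_filler())
      }
      nxt <- if (i < n) i + 1L else 1L
      if (strands[nxt] == "+") push(windows[nxt]) # tail window of next ORF
    }
  }

  lens <- vapply(blocks, nchar, integer(1))
  total <- sum(lens)
  pad <- cfg$length - total
  if (pad < 0L) {
    abort_npv(
      sprintf("infeasible packing: features need %d bp > genome length %d",
              total, cfg$length),
      "infeasible_packing"
    )
  }
  if (pad > 0L) {
    # grow the last filler-adjacent point: append padding filler before the
    # final block (keeps ORF1 at position 1 and its window at the genome end)
    parts <- compose_filler(pad, cfg$gc)
    at <- length(blocks) # insert before final block
    blocks <- append(blocks, lapply(parts, `[[`, "seq"), after = at - 1L)
    block_mutable <- append(block_mutable, lapply(parts, `[[`, "mutable"),
                            after = at - 1L)
    # re-link feature block indices shifted by the insertion
    shift_n <- length(parts)
    relink <- function(fc) {
      if (!is.null(fc) && fc$block >= at) fc$block <- fc$block + shift_n
      fc
    }
    orf_coord <- lapply(orf_coord, relink)
    hr_coord <- lapply(hr_coord, relink)
    lens <- vapply(blocks, nchar, integer(1))
  }
  starts <- cumsum(c(1L, lens[-length(lens)]))

  seq_full <- paste(unlist(blocks), collapse = "")
  stopifnot(nchar(seq_full) == cfg$length)

  # --- GC adjustment on mutable filler -------------------------------------
  mutable_pos <- unlist(purrr::map(which(unlist(block_mutable)), function(b) {
    seq.int(starts[b], starts[b] + lens[b] - 1L)
  }))
  seq_full <- adjust_gc(seq_full, cfg$gc, mutable_pos)

  g <- genome("sim_genome", seq_full, circular = TRUE)

  # --- truth tables ---------------------------------------------------------
  empty_orfs <- orf_record(1, 3)[0, ]
  orfs <- dplyr::bind_rows(empty_orfs, purrr::map_dfr(seq_len(n), function(i) {
    s <- starts[orf_coord[[i]]$block]
    orf_record(s, s + nchar(bodies[i]) - 1L, strands[i], orf_id = i,
               name = paste0("gene", i),
               annotation_basis = c(
                 core = "core_gene", alpha_conserved = "alphabaculovirus_conserved",
                 other = "homolog"
               )[[source_tags[i]]])
  }))
  homology <- tibble::tibble(
    orf_key = paste(orfs$start, orfs$end, orfs$strand, sep = ":"),
    homolog_name = orfs$name,
    source_tag = source_tags
  )
  empty_hrs <- tibble::tibble(
    hr_id = character(), region_start = integer(), region_end = integer(),
    n_units = integer(), consensus = character(), units = list()
  )
  hrs <- dplyr::bind_rows(empty_hrs, purrr::map_dfr(seq_len(cfg$n_hrs), function(h) {
    s <- starts[hr_coord[[h]]$block]
    b <- hr_blocks[[h]]
    units <- b$units
    units$start <- units$start + s - 1L
    units$end <- units$end + s - 1L
    tibble::tibble(
      hr_id = paste0("hr", h), region_start = s,
      region_end = s + nchar(b$seq) - 1L,
      n_units = nrow(units), consensus = cfg$hr_unit, units = list(units)
    )
  }))
  promoters <- tibble::tibble(
    orf_id = seq_len(n),
    labels = vapply(labels, function(x) paste(x, collapse = ","), character(1))
  )
  structure(
    list(genome = g, orfs = orfs, hrs = hrs, promoters = promoters,
         homology = homology, config = cfg),
    class = "npv_sim"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_bases <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]))
}

# Filler broken by guards so that no unguarded stretch exceeds 88 bp; starts
# and ends with a guard when long enough. Returns a list of pieces
# (seq, mutable): guards are immutable, random stretches may take GC flips.
compose_filler <- function(n, gc) {
  pieces <- list()
  add <- function(s, mutable) {
    if (nchar(s) > 0L) pieces[[length(pieces) + 1L]] <<- list(seq = s, mutable = mutable)
  }
  if (n < 2L * GUARD_LEN + 1L) {
    add(random_bases(n, gc), TRUE)
    return(pieces)
  }
  add(GUARD, FALSE)
  rem <- n - 2L * GUARD_LEN
  while (rem > 88L + GUARD_LEN) {
    add(random_bases(88L, gc), TRUE)
    add(GUARD, FALSE)
    rem <- rem - 88L - GUARD_LEN
  }
  add(random_bases(rem, gc), TRUE)
  add(GUARD, FALSE)
  pieces
}

# ATG + (n_codons - 1) non-stop codons + stop, codon bases GC-biased.
make_orf_cassette <- function(n_codons, gc) {
  stopifnot(n_codons >= 2L)
  body <- character(n_codons - 1L)
  i <- 1L
  while (i <= n_codons - 1L) {
    cand <- random_bases(3L, gc)
    if (!(cand %in% STOP_CODONS)) {
      body[i] <- cand
      i <- i + 1L
    }
  }
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

# Tandem mutated copies of the seed unit; first unit forward, later units
# reverse-complemented with probability rev_prob. Substitutions only, so all
# units keep the seed length.
make_hr_cassette <- function(unit, n_units, mutation, rev_prob) {
  L <- nchar(unit)
  units <- purrr::map_dfr(seq_len(n_units), function(j) {
    ch <- seq_chars(unit)
    hit <- stats::runif(L) < mutation
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    s <- chars_seq(ch)
    orient <- if (j > 1L && stats::runif(1) < rev_prob) "reverse" else "forward"
    tibble::tibble(
      start = (j - 1L) * L + 1L, end = j * L,
      orientation = orient,
      seq = if (orient == "reverse") revcomp(s) else s
    )
  })
  list(seq = paste(units$seq, collapse = ""), units = units)
}

# A promoter window in coding-strand orientation: two scrubbed random
# stretches separated/terminated by guards, with exactly the requested motif
# labels present anywhere in the window.
make_promoter_window <- function(want, window, gc, max_tries = 100L) {
  stopifnot(window >= 2L * GUARD_LEN + 10L)
  r2_len <- min(88L, window - 2L * GUARD_LEN - 88L)
  r1_len <- window - 2L * GUARD_LEN - max(r2_len, 0L)
  if (r2_len < 0L) { r1_len <- window - 2L * GUARD_LEN; r2_len <- 0L }
  motifs <- c(C = "CAGT", L = "TAAG", T = "TATAA")
  for (try in seq_len(max_tries)) {
    r1 <- seq_chars(random_bases(r1_len, gc))
    r2 <- if (r2_len > 0L) seq_chars(random_bases(r2_len, gc)) else character(0)
    planted <- list()
    for (lab in want) {
      m <- seq_chars(motifs[[lab]])
      reg <- if (r2_len >= length(m) && stats::runif(1) < 0.5) "r2" else "r1"
      vec_len <- if (reg == "r1") r1_len else r2_len
      at <- sample.int(vec_len - length(m) + 1L, 1L)
      if (reg == "r1") r1[at:(at + length(m) - 1L)] <- m
      else r2[at:(at + length(m) - 1L)] <- m
      planted[[length(planted) + 1L]] <- list(reg = reg, at = at, len = length(m))
    }
    win <- compose_window(r1, r2, r2_len)
    # scrub unwanted motif occurrences at positions outside planted spans
    ok <- TRUE
    for (rep_i in seq_len(50L)) {
      found <- names(PROMOTER_MOTIFS)[vapply(PROMOTER_MOTIFS, grepl, logical(1), x = win)]
      extra <- setdiff(found, want)
      if (length(extra) == 0L) break
      pat <- PROMOTER_MOTIFS[[extra[1]]]
      hit <- regexpr(pat, win)[1]
      hlen <- attr(regexpr(pat, win), "match.length")
      cand <- hit:(hit + hlen - 1L)
      cand <- cand[position_mutable(cand, r1_len, r2_len, planted)]
      if (length(cand) == 0L) { ok <- FALSE; break }
      p <- sample(cand, 1L)
      loc <- window_local(p, r1_len, r2_len)
      newb <- sample(setdiff(DNA_BASES, substr(win, p, p)), 1L)
      if (loc$reg == "r1") r1[loc$at] <- newb else r2[loc$at] <- newb
      win <- compose_window(r1, r2, r2_len)
    }
    if (!ok) next
    found <- names(PROMOTER_MOTIFS)[vapply(PROMOTER_MOTIFS, grepl, logical(1), x = win)]
    if (setequal(found, want)) return(win)
  }
  abort_npv("could not realize the requested promoter label set", "window_failure")
}

compose_window <- function(r1, r2, r2_len) {
  paste0(
    paste(r1, collapse = ""), GUARD,
    if (r2_len > 0L) paste0(paste(r2, collapse = ""), GUARD) else ""
  )
}

# window layout: [r1][guard][r2][guard]
window_local <- function(p, r1_len, r2_len) {
  if (p <= r1_len) list(reg = "r1", at = p)
  else if (p > r1_len + GUARD_LEN && p <= r1_len + GUARD_LEN + r2_len) {
    list(reg = "r2", at = p - r1_len - GUARD_LEN)
  } else list(reg = "guard", at = NA_integer_)
}

position_mutable <- function(pos, r1_len, r2_len, planted) {
  vapply(pos, function(p) {
    loc <- window_local(p, r1_len, r2_len)
    if (loc$reg == "guard") return(FALSE)
    for (pl in planted) {
      if (pl$reg == loc$reg && loc$at >= pl$at && loc$at < pl$at + pl$len) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

# Flip A/T <-> G/C at mutable positions until the GC count matches the target.
adjust_gc <- function(seq, gc, mutable_pos) {
  ch <- seq_chars(seq)
  target <- round(gc * length(ch))
  cur <- sum(ch %in% c("G", "C"))
  delta <- target - cur
  if (delta == 0L || length(mutable_pos) == 0L) return(seq)
  if (delta > 0L) {
    pool <- mutable_pos[ch[mutable_pos] %in% c("A", "T")]
    k <- min(delta, length(pool))
    if (k > 0L) {
      pick <- if (length(pool) == 1L) pool else sample(pool, k)
      ch[pick] <- sample(c("G", "C"), k, replace = TRUE)
    }
  } else {
    pool <- mutable_pos[ch[mutable_pos] %in% c("G", "C")]
    k <- min(-delta, length(pool))
    if (k > 0L) {
      pick <- if (length(pool) == 1L) pool else sample(pool, k)
      ch[pick] <- sample(c("A", "T"), k, replace = TRUE)
    }
  }
  chars_seq(ch)
}

#' Simulate a variant table with known classes
#'
#' Plants the requested number of variants of each class into a simulated
#' genome by construction: synonymous SNPs at third positions of four-fold
#' degenerate codons, nonsynonymous SNPs at second codon positions,
#' hr/intergenic SNPs outside all ORFs, in-frame indels as 3-bp deletions and
#' frameshift indels as 1- or 2-bp deletions inside ORFs. Frequencies are
#' drawn Uniform(0.10, 1.0); `n_below` additional variants get frequencies
#' below 0.10 to exercise the frequency filter.
#'
#' @param sim An `npv_sim` from [simulate_genome()].
#' @param counts Named integer vector/list over the five classes (missing
#'   classes default to 0).
#' @param seed Integer seed.
#' @param n_below Number of extra sub-threshold variants (default 0).
#' @return A tibble: `position`, `ref`, `alt`, `frequency`, `truth_class`,
#'   `below_threshold`.
#' @export
simulate_variants <- function(sim, counts = list(), seed = 1L, n_below = 0L) {
  cnt <- utils::modifyList(
    list(hr_or_intergenic = 0L, synonymous = 0L, nonsynonymous = 0L,
         inframe_indel = 0L, frameshift_indel = 0L),
    as.list(counts)
  )
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  g <- sim$genome
  glen <- genome_length(g)
  ch <- seq_chars(g$seq)
  orfs <- sim$orfs
  used <- integer(0)
  rows <- list()
  add_row <- function(pos, ref, alt, class, below = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      position = as.integer(pos), ref = ref, alt = alt,
      frequency = if (below) stats::runif(1, 0.01, 0.0999)
                  else stats::runif(1, 0.101, 1.0),
      truth_class = class, below_threshold = below
    )
    used <<- c(used, seq.int(pos, pos + nchar(ref) - 1L))
  }
  fourfold_prefixes <- c("GC", "GG", "CC", "AC", "GT", "TC", "CG", "CT")
  pick_codon_site <- function() {
    # a random internal codon of a random ORF; returns forward coordinates of
    # the codon's three bases in coding order plus the strand
    i <- sample.int(nrow(orfs), 1L)
    o <- orfs[i, ]
    n_cod <- o$aa_length
    cidx <- sample(2:(n_cod), 1L) # skip the start codon
    if (o$strand == "+") {
      p1 <- o$start + (cidx - 1L) * 3L
      list(pos = c(p1, p1 + 1L, p1 + 2L), strand = "+", orf = o)
    } else {
      p1 <- o$end - (cidx - 1L) * 3L
      list(pos = c(p1, p1 - 1L, p1 - 2L), strand = "-", orf = o)
    }
  }
  codon_at <- function(site) {
    b <- ch[wrap_pos(site$pos, glen)]
    if (site$strand == "-") b <- unname(COMPLEMENT[b])
    paste(b, collapse = "")
  }
  draw <- function(class, n_want) {
    got <- 0L
    tries <- 0L
    while (got < n_want && tries < n_want * 1000L) {
      tries <- tries + 1L
      if (class == "synonymous") {
        site <- pick_codon_site()
        cod <- codon_at(site)
        if (!substr(cod, 1, 2) %in% fourfold_prefixes) next
        p <- wrap_pos(site$pos[3], glen)
        if (p %in% used) next
        old_coding <- substr(cod, 3, 3)
        new_coding <- sample(setdiff(DNA_BASES, old_coding), 1L)
        ref <- ch[p]
        alt <- if (site$strand == "-") unname(COMPLEMENT[new_coding]) else new_coding
        add_row(p, ref, alt, class)
        got <- got + 1L
      } else if (class == "nonsynonymous") {
        site <- pick_codon_site()
        cod <- codon_at(site)
        old_coding <- substr(cod, 2, 2)
        new_coding <- sample(setdiff(DNA_BASES, old_coding), 1L)
        new_cod <- cod
        substr(new_cod, 2, 2) <- new_coding
        if (new_cod %in% STOP_CODONS) next
        if (codons_to_aa(new_cod) == codons_to_aa(cod)) next
        p <- wrap_pos(site$pos[2], glen)
        if (p %in% used) next
        ref <- ch[p]
        alt <- if (site$strand == "-") unname(COMPLEMENT[new_coding]) else new_coding
        add_row(p, ref, alt, class)
        got <- got + 1L
      } else if (class == "hr_or_intergenic") {
        p <- sample.int(glen, 1L)
        if (p %in% used || position_in_orfs(p, orfs, glen)) next
        ref <- ch[p]
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        add_row(p, ref, alt, class)
        got <- got + 1L
      } else { # indels: deletion of k bases anchored at p
        k <- if (class == "inframe_indel") 3L else sample(1:2, 1L)
        site <- pick_codon_site()
        o <- site$orf
        if (o$end - o$start < 30L) next
        p <- sample(seq(o$start + 3L, o$end - k - 3L), 1L)
        if (p > glen || any(seq.int(p, p + k) %in% used)) next
        # footprint must stay inside the ORF
        if (p + k > o$end) next
        ref <- paste(ch[seq.int(p, p + k)], collapse = "")
        alt <- ch[p]
        add_row(p, ref, alt, class)
        got <- got + 1L
      }
    }
    if (got < n_want) {
      abort_npv(sprintf("could not place %d %s variants", n_want, class),
                "variant_placement")
    }
  }
  for (cl in names(cnt)) {
    if (cnt[[cl]] > 0L) {
      if (cl != "hr_or_intergenic" && nrow(orfs) == 0L) {
        abort_npv("ORF-dependent variant classes need planted ORFs", "no_orfs")
      }
      draw(cl, cnt[[cl]])
    }
  }
  if (n_below > 0L) {
    got <- 0L
    while (got < n_below) {
      p <- sample.int(glen, 1L)
      if (p %in% used || position_in_orfs(p, orfs, glen)) next
      ref <- ch[p]
      add_row(p, ref, sample(setdiff(DNA_BASES, ref), 1L),
              "hr_or_intergenic", below = TRUE)
      got <- got + 1L
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      position = integer(), ref = character(), alt = character(),
      frequency = numeric(), truth_class = character(),
      below_threshold = logical()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$position)
}

position_in_orfs <- function(p, orfs, glen) {
  if (nrow(orfs) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(orfs)), function(j) {
    interval_overlap(p, p, orfs$start[j], orfs$end[j], glen) > 0L
  }, logical(1)))
}

#' Simulate sequence evolution with a known distance or tree
#'
#' Evolves a root sequence under the Kimura 2-parameter nucleotide model
#' (transition/transversion rate ratio `kappa`) or an empirical amino-acid
#' model (e.g. JTT, optionally with discrete-gamma site rates), either along
#' a single branch of length `t` or down a tree. No indels are introduced, so
#' the output is an alignment by construction.
#'
#' @param root_seq Root nucleotide or amino-acid string.
#' @param tree_or_t A single branch length (numeric) or an `ape::phylo` tree
#'   / Newick string with branch lengths in substitutions/site.
#' @param model `"K2P"` or an [aa_model()] object.
#' @param seed Integer seed.
#' @param kappa Transition/transversion rate ratio for K2P (default 2).
#' @param gamma_shape Optional gamma shape for site-rate heterogeneity
#'   (amino-acid models; rates are drawn once per site and shared across
#'   branches).
#' @return Named character vector of aligned sequences: `ancestor`/`derived`
#'   for a single branch, or one entry per tip for a tree.
#' @export
evolve <- function(root_seq, tree_or_t, model = "K2P", seed = 1L,
                   kappa = 2, gamma_shape = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n_sites <- nchar(root_seq)
  site_rates <- if (is.null(gamma_shape)) {
    rep(1, n_sites)
  } else {
    sample(discrete_gamma_rates(gamma_shape, 4L), n_sites, replace = TRUE)
  }
  step <- function(seq, t) {
    if (t == 0) return(seq)
    if (identical(model, "K2P")) {
      evolve_k2p_branch(seq, t, kappa, site_rates)
    } else {
      evolve_aa_branch(seq, t, model, site_rates)
    }
  }
  if (is.numeric(tree_or_t) && length(tree_or_t) == 1L) {
    return(c(ancestor = root_seq, derived = step(root_seq, tree_or_t)))
  }
  tree <- if (inherits(tree_or_t, "phylo")) tree_or_t else ape::read.tree(text = tree_or_t)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_seq
  # preorder traversal
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    seqs[[child]] <- step(seqs[[par]], ord$edge.length[e])
  }
  stats::setNames(
    vapply(seq_len(ntip), function(i) seqs[[i]], character(1)),
    tree$tip.label
  )
}

# K80 transition-probability step, vectorized over sites.
evolve_k2p_branch <- function(seq, t, kappa, site_rates) {
  alpha <- kappa / (kappa + 2)
  beta <- 1 / (kappa + 2)
  ch <- seq_chars(seq)
  idx <- match(ch, DNA_BASES)
  out <- ch
  ts_partner <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  for (r in unique(site_rates)) {
    sel <- which(site_rates == r)
    e1 <- exp(-4 * beta * t * r)
    e2 <- exp(-2 * (alpha + beta) * t * r)
    p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1 # each of two transversions
    u <- stats::runif(length(sel))
    cur <- idx[sel]
    new <- cur
    ts_hit <- u >= p_same & u < p_same + p_ts
    tv1 <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
    tv2 <- u >= p_same + p_ts + p_tv
    new[ts_hit] <- ts_partner[cur[ts_hit]]
    # transversion partners: the two bases of the other chemical class
    tv_a <- c(2L, 1L, 2L, 1L) # A->C, C->A, G->C, T->A
    tv_b <- c(4L, 3L, 4L, 3L) # A->T, C->G, G->T, T->G
    new[tv1] <- tv_a[cur[tv1]]
    new[tv2] <- tv_b[cur[tv2]]
    idx[sel] <- new
  }
  chars_seq(DNA_BASES[idx])
}

evolve_aa_branch <- function(seq, t, model, site_rates) {
  ch <- seq_chars(seq)
  idx <- match(ch, AA_ORDER)
  for (r in unique(site_rates)) {
    sel <- which(site_rates == r)
    P <- aa_transition_prob(model, t * r)
    for (b in unique(idx[sel])) {
      s2 <- sel[idx[sel] == b]
      idx[s2] <- sample.int(20L, length(s2), replace = TRUE, prob = P[b, ])
    }
  }
  chars_seq(AA_ORDER[idx])
}

#' Random root sequence for simulations
#' @param n Length.
#' @param alphabet `"dna"` (optionally GC-biased) or `"aa"` (frequencies from
#'   `model`).
#' @param gc GC fraction for DNA roots.
#' @param model An [aa_model()] whose stationary frequencies seed amino-acid
#'   roots.
#' @return A random sequence string. Uses the current RNG stream.
#' @export
random_root <- function(n, alphabet = c("dna", "aa"), gc = 0.5, model = NULL) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    random_bases(n, gc)
  } else {
    pi <- if (is.null(model)) rep(1 / 20, 20) else model$pi
    chars_seq(sample(AA_ORDER, n, replace = TRUE, prob = pi))
  }
}
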