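# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately use naive walking/looping implementations,
# independent of the package's vectorized code paths.

HR58 <- "TTGAACTCGCTTTACAAGTTTAAATGTACTCGTAAAGCAAGATCAGTGGATGATGTCA"

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# --- six-frame ORF oracle -------------------------------------------------
# Walks every ATG codon to its stop, then keeps the longest ORF per stop
# codon (suppressing nested in-frame starts).
orf_oracle <- function(g, min_codons = 50L) {
  len <- nchar(g$seq)
  one_strand <- function(seq) {
    scan <- if (g$circular) paste0(seq, seq) else seq
    ch <- strsplit(scan, "")[[1]]
    hits <- list()
    for (f in 0:2) {
      pos <- seq.int(1L + f, length(ch) - 2L, by = 3L)
      codons <- paste0(ch[pos], ch[pos + 1L], ch[pos + 2L])
      for (i in seq_along(codons)) {
        if (codons[i] != "ATG") next
        j <- i
        while (j <= length(codons) && !codons[j] %in% c("TAA", "TAG", "TGA")) {
          j <- j + 1L
        }
        if (j > length(codons)) next
        if (j - i < min_codons) next
        sb <- pos[i]; eb <- pos[j] + 2L
        if (g$circular && (sb > len || (eb - sb + 1L) > len)) next
        hits[[length(hits) + 1L]] <- c(sb, eb)
      }
    }
    if (!length(hits)) return(data.frame(start = integer(), end = integer()))
    m <- unique(do.call(rbind, hits))
    df <- data.frame(start = m[, 1], end = m[, 2])
    # longest ORF per canonical stop
    df$stop_key <- if (g$circular) ((df$end - 1L) %% len) + 1L else df$end
    df <- df[order(df$stop_key, -(df$end - df$start)), ]
    df <- df[!duplicated(df$stop_key), ]
    df[, c("start", "end")]
  }
  fwd <- one_strand(g$seq)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- one_strand(revcomp(g$seq))
  if (nrow(rev)) {
    ns <- ((len - rev$end) %% len) + 1L
    rev <- data.frame(start = ns, end = ns + (rev$end - rev$start),
                      strand = "-")
  }
  out <- rbind(fwd, rev)
  out <- unique(out)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

orf_key_set <- function(df) {
  sort(paste(df$start, df$end, df$strand, sep = ":"))
}

# --- palindrome oracle ----------------------------------------------------
# Explicit outward walk from every center.
palindrome_oracle <- function(seq, min_arm = 3L, max_mismatch = 0L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- list(center = NA_integer_, arm_length = 0L, mismatches = NA_integer_)
  for (c0 in 1:(n - 1L)) {
    mism <- 0L
    arm <- 0L
    arm_m <- NA_integer_
    t <- 1L
    while (c0 - t + 1L >= 1L && c0 + t <= n) {
      if (comp[[ch[c0 - t + 1L]]] != ch[c0 + t]) mism <- mism + 1L
      if (mism <= max_mismatch) { arm <- t; arm_m <- mism }
      t <- t + 1L
    }
    if (arm >= min_arm && arm > best$arm_length) {
      best <- list(center = c0, arm_length = arm, mismatches = arm_m)
    }
  }
  best
}

# --- inversion-block oracle ------------------------------------------------
# Explicit loop over shared points in A order.
inversion_oracle <- function(b_indices, min_run = 2L) {
  n <- length(b_indices)
  blocks <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && b_indices[j + 1L] < b_indices[j]) j <- j + 1L
    if (j - i + 1L >= min_run) {
      blocks[[length(blocks) + 1L]] <- c(i, j)
    }
    i <- if (j > i) j else i + 1L
  }
  blocks
}

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

parity_from_perm <- function(perm) {
  tibble::tibble(
    orf_index_a = seq_along(perm),
    orf_index_b = as.integer(perm),
    shared = TRUE
  )
}

# tiny genome with one planted ORF and controlled upstream window
planted_orf_genome <- function(upstream, n_codons = 60L, downstream = 30L,
                               seed = 1L) {
  set.seed(seed)
  body <- character(n_codons - 1L)
  i <- 1L
  while (i <= n_codons - 1L) {
    cand <- random_dna(3)
    if (!cand %in% c("TAA", "TAG", "TGA")) { body[i] <- cand; i <- i + 1L }
  }
  orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
  seq <- paste0(upstream, orf, random_dna(downstream))
  list(
    genome = genome("planted", seq),
    orf = orf_record(nchar(upstream) + 1L, nchar(upstream) + nchar(orf), "+")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
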