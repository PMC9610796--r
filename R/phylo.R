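AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Empirical amino-acid substitution model
#'
#' Assembles a normalized, reversible 20-state rate matrix from empirical
#' exchangeabilities and stationary frequencies, together with its
#' eigendecomposition for fast transition probabilities. `"JTT"` uses the
#' Jones-Taylor-Thornton exchangeabilities as distributed with phangorn;
#' `"Poisson"` is the uniform-rates, uniform-frequencies special case. The
#' model interface is generic, so other empirical matrices can be dropped in
#' via `exchangeabilities`/`frequencies`.
#'
#' @param name `"JTT"` or `"Poisson"`, ignored if `exchangeabilities` given.
#' @param exchangeabilities Optional vector of 190 lower-triangle (column
#'   major) symmetric exchangeabilities in the order A R N D C Q E G H I L K
#'   M F P S T W Y V.
#' @param frequencies Optional length-20 stationary frequency vector (same
#'   order).
#' @return An object of class `npv_aa_model`.
#' @export
aa_model <- function(name = c("JTT", "Poisson"),
                     exchangeabilities = NULL, frequencies = NULL) {
  if (is.null(exchangeabilities)) {
    name <- match.arg(name)
    if (name == "JTT") {
      jtt <- get(".JTT", envir = asNamespace("phangorn"))
      exchangeabilities <- jtt$Q
      frequencies <- unname(jtt$bf)
    } else {
      exchangeabilities <- rep(1, 190)
      frequencies <- rep(1 / 20, 20)
    }
  } else {
    name <- "custom"
  }
  stopifnot(length(exchangeabilities) == 190L, length(frequencies) == 20L)
  pi <- frequencies / sum(frequencies)
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  S[lower.tri(S)] <- exchangeabilities
  S <- S + t(S)
  R <- S %*% diag(pi)
  diag(R) <- -rowSums(R)
  mu <- -sum(pi * diag(R)) # mean rate; normalize to 1 substitution/site/unit
  R <- R / mu
  sp <- sqrt(pi)
  B <- diag(sp) %*% R %*% diag(1 / sp)
  B <- (B + t(B)) / 2 # symmetrize numerically
  eig <- eigen(B, symmetric = TRUE)
  structure(
    list(name = name, pi = stats::setNames(pi, AA_ORDER), rate_matrix = R,
         eig_values = eig$values,
         eig_left = diag(1 / sp) %*% eig$vectors,
         eig_right = t(eig$vectors) %*% diag(sp)),
    class = "npv_aa_model"
  )
}

# Transition probability matrix P(t) for a model.
aa_transition_prob <- function(model, t) {
  P <- model$eig_left %*% diag(exp(model$eig_values * t)) %*% model$eig_right
  P[P < 0] <- 0
  P
}

# Equal-probability discrete gamma category rates (mean 1).
discrete_gamma_rates <- function(shape, k = 4L) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  up <- stats::pgamma(q[-1L], shape = shape + 1, rate = shape)
  lo <- stats::pgamma(q[-(k + 1L)], shape = shape + 1, rate = shape)
  k * (up - lo)
}

#' Maximum-likelihood pairwise amino-acid distance
#'
#' Estimates the evolutionary distance `t` (expected substitutions/site)
#' between two aligned amino-acid sequences by maximizing the pairwise
#' likelihood under a reversible empirical model, optionally with rate
#' heterogeneity modeled by `k = 4` discrete gamma categories. The optimum is
#' bracketed on `[1e-6, 10]` with tolerance `1e-8`; sites with a gap or
#' non-standard residue in either sequence are excluded.
#'
#' @param seq1,seq2 Equal-length aligned amino-acid strings.
#' @param model An [aa_model()] (default JTT).
#' @param gamma_shape Optional gamma shape parameter (e.g. 0.79); `NULL`
#'   disables rate heterogeneity.
#' @param k Number of discrete gamma categories (default 4).
#' @return The ML distance in substitutions/site.
#' @export
aa_distance <- function(seq1, seq2, model = aa_model("JTT"),
                        gamma_shape = NULL, k = 4L) {
  if (nchar(seq1) != nchar(seq2)) {
    abort_npv("aligned sequences must have equal length", "unaligned")
  }
  x <- seq_chars(toupper(seq1))
  y <- seq_chars(toupper(seq2))
  valid <- x %in% AA_ORDER & y %in% AA_ORDER
  if (!any(valid)) abort_npv("no valid aligned sites", "no_sites")
  x <- factor(x[valid], levels = AA_ORDER)
  y <- factor(y[valid], levels = AA_ORDER)
  if (all(x == y)) return(0)
  N <- table(x, y) # pattern counts
  rates <- if (is.null(gamma_shape)) 1 else discrete_gamma_rates(gamma_shape, k)
  w <- rep(1 / length(rates), length(rates))
  negll <- function(t) {
    M <- matrix(0, 20, 20)
    for (c_i in seq_along(rates)) {
      M <- M + w[c_i] * aa_transition_prob(model, rates[c_i] * t)
    }
    L <- model$pi * M # pi_x * P_xy(t)
    L[L < 1e-300] <- 1e-300
    -sum(N * log(L))
  }
  opt <- stats::optimize(negll, interval = c(1e-6, 10), tol = 1e-8)
  if (opt$minimum > 10 - 1e-3) {
    abort_npv("saturated pair: distance optimizer hit its upper bracket", "saturation")
  }
  opt$minimum
}

#' Pairwise amino-acid distance matrix
#'
#' @param alignment Named character vector of equal-length aligned amino-acid
#'   sequences.
#' @inheritParams aa_distance
#' @return A symmetric distance matrix with zero diagonal.
#' @export
aa_dist_matrix <- function(alignment, model = aa_model("JTT"),
                           gamma_shape = NULL, k = 4L) {
  n <- length(alignment)
  nm <- names(alignment)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- aa_distance(alignment[[i]], alignment[[j]],
                                        model, gamma_shape, k)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining from a symmetric distance matrix. Negative
#' branch lengths are clamped to 0 with the deficit moved to the sister
#' branch. The result is an unrooted tree.
#'
#' @param D Symmetric numeric matrix with zero diagonal and dimnames, or a
#'   `dist` object; at least 3 taxa.
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    abort_npv("distance matrix must be symmetric", "not_symmetric")
  }
  n <- nrow(D)
  if (n < 3L) abort_npv("need at least 3 taxa", "too_few_taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  node <- labels # newick fragment per active node
  key <- labels # lexicographic tie-break key
  d <- D
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    rs <- rowSums(d)
    Qm <- (n - 2) * d - outer(rs, rs, `+`)
    diag(Qm) <- Inf
    m <- min(Qm)
    cand <- which(Qm - m < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pick_keys <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    ij <- cand[order(pick_keys)[1], ]
    i <- ij[1]; j <- ij[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    new_key <- min(key[i], key[j])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    node <- c(node[keep], new_node)
    key <- c(key[keep], new_key)
    n <- n - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], fmt(ls[1]), node[2], fmt(ls[2]), node[3], fmt(ls[3]))
  ape::read.tree(text = nwk)
}

# Bipartition keys of a tree's internal edges: each key is the sorted leaf
# set on the side not containing the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicate trees containing it (0-100), attached as
#' internal node labels.
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (0 returns the tree with no
#'   support annotations).
#' @param seed Integer RNG seed; the same seed gives bit-identical supports.
#' @param dist_fun Function mapping an alignment (named character vector) to
#'   a symmetric distance matrix. Default: [aa_dist_matrix()] with the JTT
#'   model for amino-acid input, [k2p_matrix()]-style K2P distances for
#'   nucleotide input.
#' @return An `ape::phylo` tree; with `n_reps > 0`, `node.label` holds the
#'   support percentages (empty for the root).
#' @export
bootstrap_support <- function(alignment, n_reps, seed, dist_fun = NULL) {
  if (is.null(dist_fun)) dist_fun <- default_dist_fun(alignment)
  tree0 <- nj_tree(dist_fun(alignment))
  if (n_reps == 0L) return(tree0)
  chars <- strsplit(unname(alignment), "", fixed = TRUE)
  L <- length(chars[[1]])
  M <- do.call(rbind, chars)
  rownames(M) <- names(alignment)
  keys0 <- tree_bipartitions(tree0)
  counts <- stats::setNames(numeric(length(keys0)), keys0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    aln_r <- apply(M[, idx, drop = FALSE], 1, paste, collapse = "")
    tr <- nj_tree(dist_fun(aln_r))
    hit <- intersect(tree_bipartitions(tr), keys0)
    counts[hit] <- counts[hit] + 1
  }
  support <- round(counts / n_reps * 100)
  # attach supports to the matching internal nodes of tree0
  tips <- tree0$tip.label
  anchor <- sort(tips)[1]
  nnode <- tree0$Nnode
  labs <- rep("", nnode)
  for (node in (length(tips) + 1L):(length(tips) + nnode)) {
    clade <- tips[unlist(phangorn::Descendants(tree0, node, "tips"))]
    if (length(clade) <= 1L || length(clade) >= length(tips) - 1L) next
    side <- if (anchor %in% clade) setdiff(tips, clade) else clade
    keyv <- paste(sort(side), collapse = "|")
    if (keyv %in% names(support)) {
      labs[node - length(tips)] <- as.character(support[[keyv]])
    }
  }
  tree0$node.label <- labs
  tree0
}

default_dist_fun <- function(alignment) {
  ch <- unique(seq_chars(paste(alignment, collapse = "")))
  if (all(ch %in% c(DNA_BASES, "N", "-"))) {
    function(aln) {
      n <- length(aln)
      nm <- names(aln)
      D <- matrix(0, n, n, dimnames = list(nm, nm))
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          D[i, j] <- D[j, i] <- k2p_distance(aln[[i]], aln[[j]])$d
        }
      }
      D
    }
  } else {
    mod <- aa_model("JTT")
    function(aln) aa_dist_matrix(aln, model = mod)
  }
}
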