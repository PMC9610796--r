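test_that("the amino-acid model is a proper normalized reversible rate matrix", {
  m <- aa_model("JTT")
  R <- m$rate_matrix
  expect_equal(unname(rowSums(R)), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(R)), 1, tolerance = 1e-12)
  # detailed balance: pi_i R_ij == pi_j R_ji
  lhs <- diag(m$pi) %*% R
  expect_equal(lhs, t(lhs), tolerance = 1e-12)
  # P(t) rows sum to 1 and P(0) is the identity
  P <- npvanno:::aa_transition_prob(m, 0.37)
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
  expect_equal(npvanno:::aa_transition_prob(m, 0), diag(20), tolerance = 1e-9)
})

test_that("ML amino-acid distances: identity, Poisson closed form, simulation recovery", {
  m <- aa_model("JTT")
  s <- strrep("ARNDCQEGHILKMFPSTWYV", 20)
  expect_equal(aa_distance(s, s, m), 0)

  # Poisson special case matches the closed form at the observed difference
  pois <- aa_model("Poisson")
  set.seed(2)
  x <- random_root(4000, "aa")
  y <- evolve(x, 0.25, model = pois, seed = 5)[2]
  p_obs <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  closed <- -19 / 20 * log(1 - 20 * p_obs / 19)
  expect_equal(aa_distance(x, y, pois), closed, tolerance = 1e-4)

  # JTT simulation recovery at t = 0.3 (checked against phangorn as an
  # independent implementation on one pair)
  set.seed(3)
  root <- random_root(3000, "aa", model = m)
  pair <- evolve(root, 0.3, model = m, seed = 11)
  d_mine <- aa_distance(pair[1], pair[2], m)
  expect_lt(abs(d_mine - 0.3), 0.03)
  aln <- phangorn::phyDat(do.call(rbind, strsplit(unname(pair), "")), type = "AA")
  d_ref <- as.matrix(phangorn::dist.ml(aln, model = "JTT"))[1, 2]
  expect_equal(d_mine, d_ref, tolerance = 1e-3)

  # repeated recovery over seeds
  errs <- vapply(1:10, function(s) {
    set.seed(s + 100)
    r <- random_root(2000, "aa", model = m)
    pr <- evolve(r, 0.3, model = m, seed = s)
    abs(aa_distance(pr[1], pr[2], m) - 0.3)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("gamma rate heterogeneity increases the estimated distance for diverged pairs", {
  m <- aa_model("JTT")
  set.seed(8)
  root <- random_root(1500, "aa", model = m)
  pair <- evolve(root, 0.5, model = m, seed = 21)
  plain <- aa_distance(pair[1], pair[2], m)
  gam <- aa_distance(pair[1], pair[2], m, gamma_shape = 0.79)
  expect_gt(gam, plain)
})

test_that("saturated pairs error instead of returning the bracket bound", {
  m <- aa_model("Poisson")
  # two i.i.d. random sequences carry (almost) no distance signal
  set.seed(4)
  x <- random_root(300, "aa")
  y <- chartr("ARNDCQEGHILKMFPSTWYV", "VYWTSPFMKLIHGEQCDNRA", x)
  expect_error(aa_distance(x, y, m), class = "npvanno_error_saturation")
})

test_that("NJ recovers additive trees exactly and resolves 3 taxa in closed form", {
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), letters[1:4])
  # recovered tree reproduces the additive distances exactly
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-9)

  D3 <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["x"]], 1)
  expect_equal(el[["y"]], 3)
  expect_equal(el[["z"]], 5)

  expect_error(nj_tree(D3[1:2, 1:2]), class = "npvanno_error_too_few_taxa")
  Dn <- D; Dn[1, 2] <- 7
  expect_error(nj_tree(Dn), class = "npvanno_error_not_symmetric")
})

test_that("NJ topology matches the reference implementation on random additive matrices", {
  for (i in 1:40) {
    set.seed(i)
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE, info = paste("matrix", i))
  }
})

test_that("taxon order does not change the NJ tree", {
  set.seed(77)
  tr <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr)
  t1 <- nj_tree(D)
  perm <- sample(7)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t1)[rownames(D), rownames(D)],
               ape::cophenetic.phylo(t2)[rownames(D), rownames(D)],
               tolerance = 1e-9)
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister", {
  # a non-additive matrix known to produce a negative branch estimate
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 0.1,
                3, 3, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic, order-invariant, and high for clear splits", {
  m <- aa_model("JTT")
  set.seed(5)
  root <- random_root(400, "aa", model = m)
  tips <- evolve(root, "((A:0.05,B:0.05):0.4,(C:0.05,D:0.05):0.4);",
                 model = m, seed = 2)
  t1 <- bootstrap_support(tips, 100, seed = 31)
  t2 <- bootstrap_support(tips, 100, seed = 31)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  t3 <- bootstrap_support(tips[c(4, 2, 3, 1)], 100, seed = 31)
  sup <- function(tr) max(suppressWarnings(as.numeric(tr$node.label)), na.rm = TRUE)
  expect_equal(sup(t1), sup(t3))
  expect_gte(sup(t1), 95)

  t0 <- bootstrap_support(tips, 0, seed = 1)
  expect_null(t0$node.label)
})
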