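test_that("exact tandem copies are recovered as one cluster at exact coordinates", {
  set.seed(2)
  filler1 <- random_dna(500)
  filler2 <- random_dna(500)
  g <- genome("t", paste0(filler1, strrep(HR58, 3), filler2))
  cl <- find_tandem_repeats(g)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$region_start, 501L)
  expect_equal(cl$region_end, 500L + 3L * nchar(HR58))
  expect_equal(cl$n_units, 3L)
  expect_equal(cl$consensus, HR58)
  expect_equal(cl$units[[1]]$orientation, rep("forward", 3))
})

test_that("mutated and reverse-oriented copies are still recovered as one cluster", {
  set.seed(5)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  units <- c(mut(HR58, 2), mut(HR58, 2), revcomp(mut(HR58, 2)), mut(HR58, 2))
  g <- genome("t", paste0(random_dna(400), paste(units, collapse = ""),
                          random_dna(400)))
  cl <- find_tandem_repeats(g)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_units, 4L)
  expect_lt(abs(cl$region_start - 401L), 9)
  expect_equal(cl$units[[1]]$orientation[3], "reverse")
})

test_that("repeat-free random sequence yields no clusters", {
  set.seed(31)
  fp <- 0
  for (rep in 1:20) {
    g <- genome("r", random_dna(10000))
    fp <- fp + nrow(find_tandem_repeats(g))
  }
  expect_equal(fp, 0)
})

test_that("consensus building takes the position-wise majority with lexicographic ties", {
  c1 <- build_consensus(rep(HR58, 3))
  expect_equal(c1$consensus, HR58)
  expect_equal(ncol(c1$freq), nchar(HR58))
  expect_true(all(colSums(c1$freq) == 3))

  c2 <- build_consensus(c("ACGT", "ACGA", "ACGT"))
  expect_equal(c2$consensus, "ACGT")
  expect_equal(unname(c2$freq["T", 4]), 2L)
  expect_equal(unname(c2$freq["A", 4]), 1L)

  # tie at a position: lexicographically smallest base wins
  c3 <- build_consensus(c("AAAA", "AAAC", "GAAC", "GAAA"))
  expect_equal(substr(c3$consensus, 1, 1), "A")
  expect_equal(substr(c3$consensus, 4, 4), "A")

  expect_error(build_consensus(character(0)), class = "npvanno_error_no_units")

  # tidy() produces a per-position long table with fractions
  td <- tidy(c2)
  expect_equal(nrow(td), 16)
  expect_true(all(abs(tapply(td$fraction, td$position, sum) - 1) < 1e-12))
})

test_that("consensus recovery from noisy copies succeeds in at least 95% of seeds", {
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    units <- vapply(1:6, function(i) {
      ch <- strsplit(HR58, "")[[1]]
      hit <- runif(length(ch)) < 0.05
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(ch, collapse = "")
    }, character(1))
    cons <- build_consensus(units)$consensus
    hd <- sum(strsplit(cons, "")[[1]] != strsplit(HR58, "")[[1]])
    if (hd <= 2) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("unequal-length units are aligned onto the consensus columns", {
  short <- paste0(substr(HR58, 1, 30), substr(HR58, 32, 58)) # 1-bp deletion
  cc <- build_consensus(c(HR58, HR58, short))
  expect_equal(cc$consensus, HR58)
  expect_equal(ncol(cc$freq), nchar(HR58))
})

test_that("palindrome scoring matches the canonical example and the exhaustive oracle", {
  p <- palindrome_score("GAATTC")
  expect_equal(p$center, 3L)
  expect_equal(p$arm_length, 3L)
  expect_equal(p$mismatches, 0L)

  # A pairs with T, not A: no arm at zero mismatches
  expect_equal(palindrome_score("AAAAAA", max_mismatch = 0)$arm_length, 0L)

  set.seed(19)
  for (rep in 1:40) {
    s <- random_dna(sample(6:59, 1))
    ma <- sample(0:2, 1)
    got <- palindrome_score(s, min_arm = 3, max_mismatch = ma)
    exp <- palindrome_oracle(s, min_arm = 3, max_mismatch = ma)
    expect_equal(got$arm_length, exp$arm_length, info = s)
    if (got$arm_length > 0) {
      expect_equal(got$center, exp$center, info = s)
      expect_equal(got$mismatches, exp$mismatches, info = s)
    }
  }
})

test_that("hr classification filters on unit count, consensus length, and palindrome arm", {
  set.seed(23)
  g <- genome("t", paste0(random_dna(300), strrep(HR58, 2), random_dna(300)))
  cl <- find_tandem_repeats(g)
  hrs <- classify_hrs(cl)
  expect_equal(nrow(hrs), 1)
  expect_equal(hrs$hr_id, "hr1")
  expect_gte(hrs$pal_arm, 3)

  # demanding an unrealistically long palindrome arm rejects the cluster
  expect_equal(nrow(classify_hrs(cl, min_arm = 25)), 0)
  # a cluster of 5 units fails a max_units = 4 ceiling
  g5 <- genome("t", paste0(random_dna(300), strrep(HR58, 5), random_dna(300)))
  cl5 <- find_tandem_repeats(g5)
  expect_equal(nrow(classify_hrs(cl5)), 1)
  expect_equal(nrow(classify_hrs(cl5, max_units = 4)), 0)
})

test_that("every unit stays within the divergence ceiling of its consensus", {
  sim <- simulate_genome(list(length = 15000L, n_orfs = 8L, n_hrs = 3L), seed = 41)
  cl <- find_tandem_repeats(sim$genome)
  for (i in seq_len(nrow(cl))) {
    cons <- cl$consensus[i]
    expect_true(nchar(cons) >= 40 && nchar(cons) <= 80)
    u <- cl$units[[i]]
    for (j in seq_len(nrow(u))) {
      s <- if (u$orientation[j] == "reverse") revcomp(u$seq[j]) else u$seq[j]
      d <- utils::adist(s, cons)[1, 1]
      expect_lte(d, 0.25 * nchar(cons))
    }
  }
})

test_that("detection is invariant under genome rotation and reverse complement", {
  sim <- simulate_genome(list(length = 15000L, n_orfs = 8L, n_hrs = 2L), seed = 47)
  g <- sim$genome
  len <- genome_length(g)
  hrs <- classify_hrs(find_tandem_repeats(g))
  expect_equal(nrow(hrs), 2)

  gr <- rotate_to_origin(g, 4000L)
  hrs_rot <- classify_hrs(find_tandem_repeats(gr))
  mapped <- sort(coord_map(gr)(hrs$region_start))
  expect_equal(nrow(hrs_rot), nrow(hrs))
  expect_true(all(abs(sort(hrs_rot$region_start) - mapped) <= 8))

  grc <- genome(g$id, revcomp(g$seq), circular = TRUE)
  hrs_rc <- classify_hrs(find_tandem_repeats(grc))
  mapped_rc <- sort(len - hrs$region_end + 1)
  expect_equal(nrow(hrs_rc), nrow(hrs))
  expect_true(all(abs(sort(hrs_rc$region_start) - mapped_rc) <= 8))
})
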