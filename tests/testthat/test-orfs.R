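test_that("minimal ORFs are called with correct strand and length", {
  g <- genome("t", "ATGAAATAA")
  got <- find_orfs(g, min_codons = 2)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 1L)
  expect_equal(got$end, 9L)
  expect_equal(got$strand, "+")
  expect_equal(got$aa_length, 2L)

  # reverse complement: same ORF on the minus strand, same peptide
  grc <- genome("t", revcomp(g$seq))
  got_rc <- find_orfs(grc, min_codons = 2)
  expect_equal(got_rc$strand, "-")
  expect_equal(translate_orf(got_rc[1, ], grc), translate_orf(got[1, ], g))

  # below the default 50-codon floor nothing is reported
  expect_equal(nrow(find_orfs(g)), 0)
})

test_that("find_orfs matches the brute-force six-frame oracle on random genomes", {
  set.seed(11)
  for (rep in 1:8) {
    circ <- rep %% 2 == 0
    g <- genome(paste0("r", rep), random_dna(5000, gc = 0.38), circular = circ)
    mc <- sample(c(10L, 25L, 50L), 1)
    expect_equal(
      orf_key_set(find_orfs(g, min_codons = mc)),
      orf_key_set(orf_oracle(g, min_codons = mc)),
      info = paste("rep", rep, "circular", circ)
    )
  }
})

test_that("strand symmetry: calls on revcomp equal coordinate-mapped calls", {
  set.seed(12)
  g <- genome("s", random_dna(4000, gc = 0.35))
  len <- genome_length(g)
  a <- find_orfs(g, min_codons = 20)
  b <- find_orfs(genome("s", revcomp(g$seq)), min_codons = 20)
  mapped <- data.frame(
    start = len - b$end + 1L, end = len - b$start + 1L,
    strand = ifelse(b$strand == "+", "-", "+")
  )
  expect_equal(orf_key_set(a), orf_key_set(mapped))
})

test_that("junction-spanning ORFs on circular genomes are found once with end > length", {
  set.seed(13)
  orf_nt <- paste0("ATG", strrep("GCT", 80), "TAA")
  filler <- paste0("TTAATTAATTAA", random_dna(300), "TTAATTAATTAA")
  seq0 <- paste0(orf_nt, filler)
  # rotate so the ORF straddles the junction
  g <- rotate_to_origin(genome("c", seq0, circular = TRUE), 120)
  got <- find_orfs(g, min_codons = 50)
  wrapped <- got[got$end > genome_length(g), ]
  expect_equal(nrow(wrapped), 1)
  expect_equal(wrapped$aa_length, 81L)
  expect_equal(translate_orf(wrapped[1, ], g), strsplit(paste0("M", strrep("A", 80)), NULL) |> unlist() |> paste(collapse = ""))
  # the same ORF is not double-reported
  expect_equal(sum(got$aa_length == 81), 1)
})

test_that("translation and molecular weight follow the standard code and average masses", {
  # aa_length arithmetic from span
  expect_equal(orf_record(11799, 12035, "-")$aa_length, 78L)
  expect_equal(orf_record(36077, 36721, "-")$aa_length, 214L)
  expect_error(orf_record(1, 9.5), class = "npvanno_error_bad_span")
  expect_error(orf_record(10, 6), class = "npvanno_error_bad_span")

  g <- genome("t", "ATGGCTAAATAA")
  o <- find_orfs(g, min_codons = 2)
  expect_equal(translate_orf(o[1, ], g), "MAK")

  # internal stop is an error
  gi <- genome("t", "ATGTAAGCTTAA")
  oi <- orf_record(1, 12, "+")
  expect_error(translate_orf(oi, gi), class = "npvanno_error_internal_stop")

  expect_equal(molecular_weight("AAA"), 231.2517, tolerance = 1e-6)
  expect_equal(molecular_weight_kda(strrep("A", 100)), 7.1)
})

test_that("annotation filter applies homology precedence, the 75-bp overlap boundary, and the length tie-break", {
  g <- genome("t", strrep("A", 2000))
  keep_all <- function(o, g) TRUE

  orf <- orf_record(101, 400, "+") # 100 codons
  hr75 <- tibble::tibble(region_start = 326L, region_end = 900L)
  hr76 <- tibble::tibble(region_start = 325L, region_end = 900L)
  expect_equal(nrow(annotate_orfs(orf, g, hrs = hr75, coding_predicate = keep_all)), 1)
  expect_equal(nrow(annotate_orfs(orf, g, hrs = hr76, coding_predicate = keep_all)), 0)

  # full containment in an hr removes even without >75 bp logic
  hr_cont <- tibble::tibble(region_start = 1L, region_end = 500L)
  expect_equal(nrow(annotate_orfs(orf, g, hrs = hr_cont, coding_predicate = keep_all)), 0)

  # homology overrides the hr rules
  hom <- tibble::tibble(orf_key = "101:400:+", homolog_name = "polh",
                        source_tag = "core")
  kept <- annotate_orfs(orf, g, hrs = hr_cont, homology = hom,
                        coding_predicate = keep_all)
  expect_equal(kept$annotation_basis, "core_gene")
  expect_equal(kept$name, "polh")

  # overlap with a longer annotated ORF: boundary at 75 bp
  long_orf <- orf_record(1, 600, "+")    # 199 codons
  short75 <- orf_record(526, 825, "+")   # overlap 75
  short76 <- orf_record(525, 824, "+")   # overlap 76
  hom_long <- tibble::tibble(orf_key = "1:600:+", homolog_name = "big",
                             source_tag = "other")
  a75 <- annotate_orfs(dplyr::bind_rows(long_orf, short75), g,
                       homology = hom_long, coding_predicate = keep_all)
  expect_equal(nrow(a75), 2)
  a76 <- annotate_orfs(dplyr::bind_rows(long_orf, short76), g,
                       homology = hom_long, coding_predicate = keep_all)
  expect_equal(nrow(a76), 1)

  # equal-length heavy overlap: exactly one kept, the earlier start
  e1 <- orf_record(101, 400, "+")
  e2 <- orf_record(201, 500, "+") # overlap 200 bp, same 100 codons
  kept_tie <- annotate_orfs(dplyr::bind_rows(e2, e1), g,
                            coding_predicate = keep_all)
  expect_equal(nrow(kept_tie), 1)
  expect_equal(kept_tie$start, 101L)

  # the coding predicate gates ab initio ORFs
  expect_equal(nrow(annotate_orfs(orf, g, coding_predicate = function(o, g) FALSE)), 0)
})

test_that("renumbering assigns ids along the genome and rejects duplicate starts", {
  o <- dplyr::bind_rows(
    orf_record(1, 300, "+"), orf_record(500, 802, "+"), orf_record(310, 486, "-")
  )
  r <- renumber_orfs(o[c(2, 1, 3), ]) # shuffled input
  expect_equal(r$orf_id, 1:3)
  expect_equal(r$start, c(1L, 310L, 500L))
  r2 <- renumber_orfs(o)
  expect_equal(r2$orf_id, r$orf_id)
  expect_error(renumber_orfs(dplyr::bind_rows(orf_record(1, 300, "+"),
                                              orf_record(1, 150, "+"))),
               class = "npvanno_error_duplicate_start")
})

test_that("every returned ORF has a clean translation and a span divisible by 3", {
  set.seed(17)
  g <- genome("p", random_dna(6000, gc = 0.4), circular = TRUE)
  orfs <- find_orfs(g, min_codons = 15)
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    expect_equal((orfs$end[i] - orfs$start[i] + 1L) %% 3L, 0L)
    aa <- translate_orf(orfs[i, ], g)
    expect_equal(nchar(aa), orfs$aa_length[i])
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})
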