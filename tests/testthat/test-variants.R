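test_that("frequency filtering is strictly greater than the threshold", {
  v <- tibble::tibble(position = 1:4, ref = "A", alt = "G",
                      frequency = c(0.10, 0.101, 1.0, 0.05))
  got <- filter_variants(v)
  expect_equal(got$position, c(2L, 3L))
  expect_equal(nrow(filter_variants(v[0, ])), 0)
  expect_equal(nrow(filter_variants(dplyr::mutate(v, frequency = 1.0))), 4)
  expect_error(filter_variants(dplyr::mutate(v, frequency = 1.5)),
               class = "npvanno_error_bad_frequency")
})

test_that("SNP classification translates codons strand-aware", {
  # plus strand: GCT -> GCC at the wobble position is synonymous (Ala)
  g <- genome("t", paste0("ATG", "GCT", "AAA", "TAA", strrep("AC", 30)))
  orfs <- orf_record(1, 12, "+")
  v <- tibble::tibble(position = 6L, ref = "T", alt = "C", frequency = 0.5)
  expect_equal(classify_variants(v, g, orfs)$class, "synonymous")

  # second codon position: nonsynonymous
  v2 <- tibble::tibble(position = 5L, ref = "C", alt = "A", frequency = 0.5)
  expect_equal(classify_variants(v2, g, orfs)$class, "nonsynonymous")

  # start codon A -> G changes Met: nonsynonymous
  v3 <- tibble::tibble(position = 1L, ref = "A", alt = "G", frequency = 0.5)
  expect_equal(classify_variants(v3, g, orfs)$class, "nonsynonymous")

  # the same ORF on the minus strand: forward-strand alleles are complements
  grc <- genome("t", revcomp(g$seq))
  len <- genome_length(g)
  orfs_rc <- orf_record(len - 12 + 1, len, "-")
  v4 <- tibble::tibble(position = len - 6 + 1, ref = "A", alt = "G",
                       frequency = 0.5)
  expect_equal(classify_variants(v4, grc, orfs_rc)$class, "synonymous")
})

test_that("indels classify by frame preservation and positions outside ORFs by region", {
  g <- genome("t", paste0(strrep("AC", 25), "ATG", strrep("GCT", 30), "TAA",
                          strrep("AC", 25)))
  orfs <- orf_record(51, 146, "+")
  del3 <- tibble::tibble(position = 60L, ref = "TGCT", alt = "T", frequency = 0.5)
  expect_equal(classify_variants(del3, g, orfs)$class, "inframe_indel")
  del2 <- tibble::tibble(position = 60L, ref = "TGC", alt = "T", frequency = 0.5)
  expect_equal(classify_variants(del2, g, orfs)$class, "frameshift_indel")
  ins1 <- tibble::tibble(position = 60L, ref = "T", alt = "TA", frequency = 0.5)
  expect_equal(classify_variants(ins1, g, orfs)$class, "frameshift_indel")

  # intergenic SNP
  vi <- tibble::tibble(position = 10L, ref = "C", alt = "T", frequency = 0.5)
  expect_equal(classify_variants(vi, g, orfs)$class, "hr_or_intergenic")

  # hr takes precedence over an overlapping ORF
  hrs <- tibble::tibble(region_start = 51L, region_end = 100L)
  vh <- tibble::tibble(position = 60L, ref = "C", alt = "T", frequency = 0.5)
  expect_equal(classify_variants(vh, g, orfs, hrs)$class, "hr_or_intergenic")

  # overlapping ORFs: classified against the longer one, with a warning
  orfs2 <- dplyr::bind_rows(orf_record(51, 146, "+"), orf_record(57, 86, "+"))
  # position 62 is the wobble base of the 4th codon (GCT) of the longer ORF
  expect_warning(
    got <- classify_variants(tibble::tibble(position = 62L, ref = "T",
                                            alt = "C", frequency = 0.5),
                             g, orfs2),
    "overlapping"
  )
  expect_equal(got$class, "synonymous")

  expect_error(
    classify_variants(tibble::tibble(position = 9999L, ref = "A", alt = "G",
                                     frequency = 0.5), g, orfs),
    class = "npvanno_error_bad_position"
  )
})

test_that("summaries conserve counts and keep all five classes", {
  s0 <- summarize_variants(tibble::tibble(class = character(0)))
  expect_equal(sum(s0$n), 0)
  expect_equal(nrow(s0), 5)

  sim <- simulate_genome(list(length = 15000L, n_orfs = 10L, n_hrs = 2L), seed = 13)
  v <- simulate_variants(sim, counts = list(synonymous = 10, nonsynonymous = 12,
                                            hr_or_intergenic = 8,
                                            inframe_indel = 2,
                                            frameshift_indel = 2),
                         seed = 3, n_below = 5)
  vf <- filter_variants(v)
  expect_equal(nrow(vf), 34)       # sub-threshold variants removed
  expect_equal(nrow(v) - nrow(vf), 5)
  vc <- classify_variants(vf, sim$genome, sim$orfs, sim$hrs)
  expect_equal(vc$class, vc$truth_class) # zero misclassification
  s <- summarize_variants(vc)
  expect_equal(sum(s$n), nrow(vf))
  expect_equal(s$n[s$class == "synonymous"], 10L)
  expect_equal(s$n[s$class == "nonsynonymous"], 12L)
})

test_that("classification is invariant under genome rotation", {
  sim <- simulate_genome(list(length = 15000L, n_orfs = 10L, n_hrs = 2L), seed = 19)
  v <- filter_variants(simulate_variants(sim, counts = list(synonymous = 8,
                                                            nonsynonymous = 8,
                                                            hr_or_intergenic = 6),
                                         seed = 4))
  base <- classify_variants(v, sim$genome, sim$orfs, sim$hrs)$class

  gr <- rotate_to_origin(sim$genome, 6001L)
  cm <- coord_map(gr)
  shift_iv <- function(df, s_col, e_col) {
    df[[paste0(s_col, "_n")]] <- cm(df[[s_col]])
    df[[e_col]] <- df[[paste0(s_col, "_n")]] + (df[[e_col]] - df[[s_col]])
    df[[s_col]] <- df[[paste0(s_col, "_n")]]
    df[[paste0(s_col, "_n")]] <- NULL
    df
  }
  orfs_r <- shift_iv(sim$orfs, "start", "end")
  hrs_r <- shift_iv(sim$hrs, "region_start", "region_end")
  v_r <- dplyr::mutate(v, position = cm(.data$position))
  got <- classify_variants(v_r, gr, orfs_r, hrs_r)$class
  expect_equal(got, base)
})

test_that("variant tables round-trip through the TSV reader", {
  v <- tibble::tibble(position = c(10L, 50L), ref = c("A", "ACG"),
                      alt = c("G", "A"), frequency = c(0.4, 0.9))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(v, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_variants(f)
  expect_equal(as.data.frame(back), as.data.frame(v))
  expect_error(read_variants("no/such/file.tsv"),
               class = "npvanno_error_input_not_found")
})
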