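test_that("classify_alleles partitions worked genotype configurations", {
  # homozygous donor vs heterozygous recipient: one recipient-exclusive allele
  call <- classify_alleles(genotype("D5S818", c(12, 12)),
                           genotype("D5S818", c(10, 12)))
  expect_equal(call$recipient_exclusive, 10)
  expect_length(call$donor_exclusive, 0)
  expect_equal(call$shared, 12)
  expect_true(call$informative)
  expect_false(call$fully_informative)

  # fully informative: exclusive allele on each side plus one shared
  call <- classify_alleles(genotype("FGA", c(15, 17) + 10),
                           genotype("FGA", c(14, 15) + 10))
  expect_equal(call$recipient_exclusive, 24)
  expect_equal(call$donor_exclusive, 27)
  expect_equal(call$shared, 25)
  expect_true(call$fully_informative)

  # identical genotypes carry no exclusive allele
  call <- classify_alleles(genotype("TPOX", c(11, 13)),
                           genotype("TPOX", c(11, 13)))
  expect_length(call$recipient_exclusive, 0)
  expect_length(call$donor_exclusive, 0)
  expect_equal(call$shared, c(11, 13))
  expect_false(call$informative)

  expect_error(classify_alleles(genotype("TPOX", c(8, 9)),
                                genotype("TH01", c(8, 9))),
               "TPOX.*TH01")
})

test_that("classification matches a brute-force oracle over all pairs on {8..18}", {
  gs <- all_genotypes(8:18)
  match_oracle <- TRUE
  conserved <- TRUE
  symmetric <- TRUE
  n_checked <- 0L
  for (d in gs) for (r in gs) {
    call <- classify_alleles(genotype("D18S51-R", d), genotype("D18S51-R", r))
    oracle <- oracle_classify(d, r)
    match_oracle <- match_oracle &&
      identical(call$recipient_exclusive, oracle$recipient_exclusive) &&
      identical(call$donor_exclusive, oracle$donor_exclusive) &&
      identical(call$shared, oracle$shared)

    # partition conservation
    conserved <- conserved &&
      (length(call$recipient_exclusive) + length(call$donor_exclusive) +
         length(call$shared)) == length(unique(c(d, r)))

    # symmetry: swapping roles swaps the exclusive sets
    swapped <- classify_alleles(genotype("D18S51-R", r), genotype("D18S51-R", d))
    symmetric <- symmetric &&
      identical(swapped$recipient_exclusive, call$donor_exclusive) &&
      identical(swapped$donor_exclusive, call$recipient_exclusive) &&
      identical(swapped$shared, call$shared) &&
      identical(swapped$informative, call$informative)
    n_checked <- n_checked + 1L
  }
  expect_true(match_oracle)
  expect_true(conserved)
  expect_true(symmetric)
  expect_equal(n_checked, 66L^2)
})

test_that("informative_loci filters, orders and errors as specified", {
  pair <- sibling_pair(
    "PX",
    donor = list(genotype("D5S818", c(12, 12)), genotype("TH01", c(6, 7)),
                 genotype("TPOX", c(8, 10))),
    recipient = list(genotype("D5S818", c(10, 12)), genotype("TH01", c(6, 7)),
                     genotype("TPOX", c(9, 11))))
  calls <- informative_loci(pair)
  expect_length(calls, 2L)
  # fully informative TPOX (2 recipient-exclusive) ranks before partial D5S818
  expect_equal(vapply(calls, `[[`, character(1), "locus"),
               c("TPOX", "D5S818"))

  same <- sibling_pair("PY",
                       donor = list(genotype("TH01", c(6, 7))),
                       recipient = list(genotype("TH01", c(7, 6))))
  expect_length(informative_loci(same), 0L)

  expect_error(sibling_pair("PZ",
                            donor = list(genotype("TH01", c(6, 7))),
                            recipient = list(genotype("TPOX", c(6, 7)))),
               "different loci")
})

test_that("informativeness_table computes fractions and categories", {
  panel <- default_panel()
  # single pair informative at every locus: all fractions 1
  donor <- lapply(panel, function(l) genotype(l$name, l$allele_range))
  recipient <- lapply(panel, function(l)
    genotype(l$name, c(l$allele_range[1] + 1L, l$allele_range[2] - 1L)))
  cohort <- list(sibling_pair("P1", donor, recipient))
  tab <- informativeness_table(cohort)
  expect_equal(tab$fraction, rep(1, 10))
  expect_equal(tab$category, rep("common", 10))

  # missing panel locus is an explicit error naming pair and locus
  short <- list(sibling_pair("P9",
                             donor = list(genotype("TH01", c(6, 7))),
                             recipient = list(genotype("TH01", c(6, 8)))))
  expect_error(informativeness_table(short), "P9.*D5S818")
})

test_that("genotype tables round-trip through TSV", {
  cohort <- make_table1_fixture(seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(cohort, path)
  back <- read_genotypes(path)
  expect_length(back, 20L)
  expect_equal(informativeness_table(back), informativeness_table(cohort))
  expect_equal(back[[7]]$donor$TH01$alleles, cohort[[7]]$donor$TH01$alleles)
})
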