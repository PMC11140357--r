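labelled <- function(areas, labels) {
  data.frame(peak = seq_along(areas), area = areas, label = labels)
}

test_that("simple-complement mode reproduces the worked peak arithmetic", {
  # two peaks: shared 60.6, recipient-specific 39.4 -> donor 60.6%
  res <- donor_chimerism_simple(labelled(c(60.6, 39.4),
                                         c("shared", "recipient_exclusive")),
                                locus = "D5S818")
  expect_equal(res$donor_percent, 60.6, tolerance = 1e-12)
  expect_equal(res$recipient_percent, 39.4, tolerance = 1e-12)

  # three peaks: donor-exclusive pair summing 79.4, recipient 20.6
  res3 <- donor_chimerism_simple(labelled(c(30.1, 20.6, 49.3),
                                          c("donor_exclusive",
                                            "recipient_exclusive",
                                            "donor_exclusive")),
                                 locus = "D3S1358")
  expect_equal(res3$donor_percent, 79.4, tolerance = 1e-12)

  # complete chimerism: zero recipient-exclusive area
  res0 <- donor_chimerism_simple(labelled(c(80, 0),
                                          c("shared", "recipient_exclusive")))
  expect_equal(res0$donor_percent, 100)
  expect_true("complete_chimerism" %in% res0$flags)

  expect_error(donor_chimerism_simple(labelled(100, "shared")),
               "not informative")
  expect_error(donor_chimerism_simple(labelled(c(0, 0),
                                               c("shared", "recipient_exclusive"))),
               "zero")
  # unassigned peaks are excluded from the normalization
  res_u <- donor_chimerism_simple(labelled(c(60.6, 39.4, 55),
                                           c("shared", "recipient_exclusive",
                                             "unassigned")))
  expect_equal(res_u$donor_percent, 60.6, tolerance = 1e-12)
})

test_that("paired-informative mode uses exclusive peaks only", {
  pk <- labelled(c(25, 75, 100),
                 c("recipient_exclusive", "donor_exclusive", "shared"))
  res <- donor_chimerism_paired(pk)
  expect_equal(res$recipient_percent, 25)
  expect_equal(res$donor_percent, 75)

  res0 <- donor_chimerism_paired(labelled(c(0, 42),
                                          c("recipient_exclusive",
                                            "donor_exclusive")))
  expect_equal(res0$donor_percent, 100)

  # symmetry at equal exclusive areas
  expect_equal(donor_chimerism_paired(labelled(c(33, 33),
                                               c("recipient_exclusive",
                                                 "donor_exclusive")))$donor_percent,
               50)
  expect_error(donor_chimerism_paired(labelled(c(10, 90),
                                               c("recipient_exclusive", "shared"))),
               "paired mode")

  # dosage correction halves a homozygous donor's effective area
  pkd <- labelled(c(30, 60), c("recipient_exclusive", "donor_exclusive"))
  pkd$allele <- c(10, 12)
  call <- classify_alleles(genotype("D5S818", c(12, 12)),
                           genotype("D5S818", c(10, 11)))
  resd <- donor_chimerism_paired(pkd, call = call, dosage_correct = TRUE)
  expect_equal(resd$donor_percent, 100 * 30 / 60)
})

test_that("chimerism obeys complement, monotonicity and mode-agreement laws", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    labels <- c("recipient_exclusive",
                sample(c("donor_exclusive", "shared"), k - 1, replace = TRUE))
    areas <- stats::runif(k, 0.1, 100)
    pk <- labelled(areas, labels)
    res <- donor_chimerism_simple(pk)
    rex_share <- 100 * sum(areas[labels == "recipient_exclusive"]) / sum(areas)
    expect_equal(res$donor_percent, 100 - rex_share, tolerance = 1e-9)
    expect_equal(res$donor_percent + res$recipient_percent, 100,
                 tolerance = 1e-9)

    # strictly decreasing donor percent in the recipient-exclusive area
    bigger <- pk
    bigger$area[1] <- bigger$area[1] * 1.5
    expect_lt(donor_chimerism_simple(bigger)$donor_percent, res$donor_percent)

    # with no shared peaks the two modes agree
    if (!"shared" %in% labels && "donor_exclusive" %in% labels) {
      expect_equal(donor_chimerism_paired(pk)$donor_percent,
                   res$donor_percent, tolerance = 1e-9)
    }
  }
})

test_that("aggregation reports unweighted mean and range", {
  r1 <- donor_chimerism_simple(labelled(c(60.6, 39.4),
                                        c("shared", "recipient_exclusive")), "D5S818")
  agg1 <- aggregate_chimerism(list(r1))
  expect_equal(agg1$mean_donor_percent, 60.6, tolerance = 1e-12)
  expect_equal(agg1$range_donor_percent, c(60.6, 60.6), tolerance = 1e-12)

  r2 <- donor_chimerism_simple(labelled(c(79.4, 20.6),
                                        c("donor_exclusive", "recipient_exclusive")),
                               "D3S1358")
  agg <- aggregate_chimerism(list(r1, r2))
  expect_equal(agg$mean_donor_percent, 70.0, tolerance = 1e-12)
  expect_equal(nrow(agg$per_locus), 2L)
  expect_error(aggregate_chimerism(list()), "no chimerism")
})
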