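# Shared scene builders: the two worked gel configurations used throughout
# the tests.

# two-band lane: donor homozygous (shared upper band), recipient-exclusive
# lower band
fig1_call <- function() {
  classify_alleles(genotype("D5S818", c(12, 12)),
                   genotype("D5S818", c(10, 12)))
}

# three-band lane: recipient-exclusive middle allele
fig3_call <- function() {
  classify_alleles(genotype("D3S1358", c(13, 16)),
                   genotype("D3S1358", c(14, 16)))
}

# independent brute-force allele classifier: per-allele membership scan over
# the union of both genotypes (no set operations)
oracle_classify <- function(donor_alleles, recipient_alleles) {
  union_alleles <- sort(unique(c(donor_alleles, recipient_alleles)))
  out <- list(recipient_exclusive = numeric(0), donor_exclusive = numeric(0),
              shared = numeric(0))
  for (a in union_alleles) {
    in_d <- FALSE
    for (x in donor_alleles) if (x == a) in_d <- TRUE
    in_r <- FALSE
    for (x in recipient_alleles) if (x == a) in_r <- TRUE
    if (in_d && in_r) out$shared <- c(out$shared, a)
    else if (in_r) out$recipient_exclusive <- c(out$recipient_exclusive, a)
    else out$donor_exclusive <- c(out$donor_exclusive, a)
  }
  out
}

# all unordered genotypes (allele pairs with repetition) over a label set
all_genotypes <- function(alleles) {
  gs <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    gs[[length(gs) + 1L]] <- c(alleles[i], alleles[j])
  gs
}

# synthetic single-Gaussian profile on a flat-zero baseline
gaussian_profile <- function(n, center, sigma, height) {
  height * exp(-((seq_len(n) - 1) - center)^2 / (2 * sigma^2))
}
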