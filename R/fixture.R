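# Cohort-level informativeness structure the fixture reproduces:
# per-locus informative counts out of 20 sibling pairs, panel order.
table1_counts <- function() {
  c("D5S818" = 8L, "D3S1358" = 8L, "D7S820" = 5L, "D8S1179" = 5L,
    "FGA" = 4L, "TH01" = 3L, "TPOX" = 2L, "D13S317" = 2L,
    "D18S51-R" = 1L, "D21S1411-F" = 1L)
}

# Binary pair x locus incidence matrix with fixed margins: column sums are
# the per-locus informative counts above; row sums are chosen so that every
# pair has >= 1 informative locus and per-pair counts span 1 to 8. Greedy
# (Gale-Ryser style) fill; deterministic, independent of the seed.
informative_incidence <- function() {
  col_sums <- table1_counts()
  row_sums <- c(8L, 5L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, 12L))
  stopifnot(sum(row_sums) == sum(col_sums))
  m <- matrix(0L, nrow = length(row_sums), ncol = length(col_sums),
              dimnames = list(NULL, names(col_sums)))
  cap <- row_sums
  for (j in order(-col_sums)) {
    pick <- order(-cap, seq_along(cap))[seq_len(col_sums[j])]
    if (any(cap[pick] <= 0L)) stop("infeasible informativeness margins")
    m[pick, j] <- 1L
    cap[pick] <- cap[pick] - 1L
  }
  stopifnot(all(rowSums(m) == row_sums), all(colSums(m) == col_sums))
  m
}

sample_allele <- function(locus, n = 1L) {
  r <- locus$allele_range
  sample(seq(r[1], r[2]), n, replace = TRUE)
}

# A donor/recipient genotype pair at `locus`, informative (allele sets
# differ) or not (identical allele sets), drawn from the live RNG stream.
sample_genotype_pair <- function(locus, informative) {
  if (!informative) {
    alleles <- if (stats::runif(1) < 0.4) rep(sample_allele(locus), 2L)
               else sort(sample(seq(locus$allele_range[1], locus$allele_range[2]), 2L))
    g <- genotype(locus$name, alleles)
    return(list(donor = g, recipient = g))
  }
  repeat {
    donor <- genotype(locus$name, sample_allele(locus, 2L))
    recipient <- genotype(locus$name, sample_allele(locus, 2L))
    if (!setequal(unique(donor$alleles), unique(recipient$alleles)))
      return(list(donor = donor, recipient = recipient))
  }
}

#' Generate the 20-pair sibling cohort fixture
#'
#' Builds a synthetic cohort of 20 donor/recipient sibling pairs typed at
#' the ten-locus autosomal panel whose informativeness structure matches the
#' reference cohort exactly: per-locus informative counts of
#' 8, 8, 5, 5, 4, 3, 2, 2, 1 and 1 out of 20 (i.e. 40%, 40%, 25%, 25%, 20%,
#' 15%, 10%, 10%, 5%, 5%), at least one informative locus in every pair, and
#' per-pair informative-locus counts spanning 1 to 8. Which loci are
#' informative for which pair is a fixed design; the genotypes realizing it
#' are drawn from the seeded RNG, so different seeds give different
#' genotypes with identical marginal counts.
#'
#' @param seed Integer RNG seed.
#' @param panel Named list of [str_locus()] (default [default_panel()]).
#' @return List of 20 [sibling_pair()] objects (`P01` ... `P20`).
#' @examples
#' cohort <- make_table1_fixture(seed = 1)
#' informativeness_table(cohort)
#' @export
make_table1_fixture <- function(seed = 1L, panel = default_panel()) {
  inc <- informative_incidence()
  stopifnot(all(colnames(inc) %in% names(panel)))
  with_seed(seed, {
    lapply(seq_len(nrow(inc)), function(i) {
      gs <- lapply(colnames(inc), function(loc)
        sample_genotype_pair(panel[[loc]], informative = inc[i, loc] == 1L))
      sibling_pair(sprintf("P%02d", i),
                   donor = lapply(gs, `[[`, "donor"),
                   recipient = lapply(gs, `[[`, "recipient"))
    })
  })
}

#' Generate a synthetic chimerism cohort spanning a designed range
#'
#' Renders one chimera lane per designed donor fraction and runs the full
#' densitometry-to-chimerism pipeline on each — a throughput check that the
#' pipeline covers the clinically relevant range of mixed chimerism, not a
#' reproduction of any patient series. Because the extremes put the minor
#' band near the gel method's detection limit (a ~1% component), the lanes
#' are rendered narrow and heavily loaded — the standard way of maximizing
#' the band's surface density — and quantified with a sensitive peak
#' threshold (`min_prominence_frac = 0.005`).
#'
#' @param donor_fractions Designed donor fractions in `[0, 1]`.
#' @param seed Integer RNG seed (one render seed is derived per lane).
#' @param noise_sd Render noise SD (default 1, the renderer default).
#' @return `data.frame` with `designed_percent` and recovered
#'   `donor_percent` per synthetic sample.
#' @export
make_range_cohort <- function(donor_fractions = c(0.132, 0.25, 0.50,
                                                  0.606, 0.794, 0.989),
                              seed = 1L, noise_sd = 1) {
  call <- classify_alleles(genotype("D5S818", c(12, 12)),
                           genotype("D5S818", c(10, 12)))
  res <- vapply(seq_along(donor_fractions), function(i) {
    spec <- gel_render_spec(lane_width_px = 12L, noise_sd = noise_sd,
                            seed = (seed * 1009L + i) %% .Machine$integer.max)
    scene <- make_chimera_lane(call, donor_fractions[i], spec)
    quantify_lane(scene$image, lane = 1, call = call,
                  min_prominence_frac = 0.005)$donor_percent
  }, numeric(1))
  data.frame(designed_percent = 100 * donor_fractions, donor_percent = res)
}
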