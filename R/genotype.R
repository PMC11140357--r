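#' STR genotype at one locus
#'
#' A genotype is an unordered pair of allele labels (repeat counts by
#' default, or fragment sizes in bp — compared exactly either way).
#' Homozygotes are stored as a duplicated label: they contribute a single
#' distinct allele to set logic but carry a dosage of 2 per-allele for
#' optional area correction downstream.
#'
#' @param locus Locus name (character scalar).
#' @param alleles Numeric vector of exactly two allele labels; a homozygote
#'   repeats the same label.
#' @return An object of class `str_genotype` with fields `locus`, `alleles`
#'   (sorted), and `homozygous`.
#' @examples
#' genotype("D5S818", c(12, 12))   # homozygous, single thick band on a gel
#' genotype("D5S818", c(10, 12))
#' @export
genotype <- function(locus, alleles) {
  stopifnot(is.character(locus), length(locus) == 1L, nzchar(locus))
  alleles <- as.numeric(alleles)
  if (length(alleles) != 2L || anyNA(alleles))
    stop("a genotype at ", locus, " needs exactly two allele labels")
  structure(
    list(locus = locus, alleles = sort(alleles),
         homozygous = alleles[1] == alleles[2]),
    class = "str_genotype"
  )
}

#' @export
print.str_genotype <- function(x, ...) {
  cat(sprintf("<str_genotype> %s {%s}%s\n", x$locus,
              paste(format(x$alleles, trim = TRUE), collapse = ","),
              if (x$homozygous) " hom" else ""))
  invisible(x)
}

#' Allele dosage of a genotype
#'
#' Copies carried per distinct allele: 2 for the single allele of a
#' homozygote, 1 for each allele of a heterozygote.
#'
#' @param g An [genotype()].
#' @return Named numeric vector, one entry per distinct allele.
#' @export
allele_dosage <- function(g) {
  stopifnot(inherits(g, "str_genotype"))
  tab <- table(g$alleles)
  structure(as.numeric(tab), names = names(tab))
}

#' Donor/recipient sibling pair
#'
#' Bundles the donor's and the recipient's genotypes, typed at the same
#' loci; the unit on which informative loci are identified.
#'
#' @param pair_id Pair identifier (character scalar).
#' @param donor,recipient Lists of [genotype()] objects, one per locus.
#' @return An object of class `sibling_pair`.
#' @export
sibling_pair <- function(pair_id, donor, recipient) {
  stopifnot(is.character(pair_id), length(pair_id) == 1L, nzchar(pair_id))
  name_by_locus <- function(gs) {
    stopifnot(all(vapply(gs, inherits, logical(1), "str_genotype")))
    names(gs) <- vapply(gs, `[[`, character(1), "locus")
    if (anyDuplicated(names(gs)))
      stop("pair ", pair_id, ": duplicated locus in genotype list")
    gs
  }
  donor <- name_by_locus(donor)
  recipient <- name_by_locus(recipient)
  if (!setequal(names(donor), names(recipient)))
    stop("pair ", pair_id, ": donor and recipient typed at different loci")
  recipient <- recipient[names(donor)]
  structure(list(pair_id = pair_id, donor = donor, recipient = recipient),
            class = "sibling_pair")
}

#' @export
print.sibling_pair <- function(x, ...) {
  cat(sprintf("<sibling_pair> %s, %d loci: %s\n", x$pair_id,
              length(x$donor), paste(names(x$donor), collapse = ", ")))
  invisible(x)
}

#' Classify alleles as exclusive or shared between donor and recipient
#'
#' Partitions the union of the two genotypes' allele sets into
#' recipient-exclusive, donor-exclusive and shared alleles. A locus is
#' *informative* when at least one exclusive allele exists in either
#' direction, and *fully informative* when both individuals carry an
#' exclusive allele.
#'
#' @param donor,recipient [genotype()] objects at the same locus.
#' @return An object of class `informative_call`: a list with fields
#'   `locus`, `recipient_exclusive`, `donor_exclusive`, `shared` (numeric
#'   allele vectors), `informative`, `fully_informative`, and the two input
#'   genotypes (`donor`, `recipient`) for dosage lookups.
#' @examples
#' classify_alleles(genotype("D5S818", c(12, 12)),
#'                  genotype("D5S818", c(10, 12)))
#' @export
classify_alleles <- function(donor, recipient) {
  stopifnot(inherits(donor, "str_genotype"), inherits(recipient, "str_genotype"))
  if (donor$locus != recipient$locus)
    stop("locus mismatch: donor typed at ", donor$locus,
         ", recipient at ", recipient$locus)
  d <- unique(donor$alleles)
  r <- unique(recipient$alleles)
  call <- list(
    locus = donor$locus,
    recipient_exclusive = sort(setdiff(r, d)),
    donor_exclusive = sort(setdiff(d, r)),
    shared = sort(intersect(d, r)),
    donor = donor,
    recipient = recipient
  )
  call$informative <- length(call$recipient_exclusive) > 0 ||
    length(call$donor_exclusive) > 0
  call$fully_informative <- length(call$recipient_exclusive) > 0 &&
    length(call$donor_exclusive) > 0
  structure(call, class = "informative_call")
}

#' @export
print.informative_call <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(format(v, trim = TRUE), collapse = ",") else "-"
  cat(sprintf(
    "<informative_call> %s: recipient-exclusive {%s}, donor-exclusive {%s}, shared {%s} [%s]\n",
    x$locus, fmt(x$recipient_exclusive), fmt(x$donor_exclusive), fmt(x$shared),
    if (x$fully_informative) "fully informative"
    else if (x$informative) "informative" else "not informative"))
  invisible(x)
}

#' Informative loci of a sibling pair
#'
#' Classifies every typed locus and returns the informative ones, ordered by
#' usefulness: fully informative loci first, then by the number of
#' recipient-exclusive alleles (the signal needed to see returning recipient
#' haematopoiesis), ties broken by the pair's locus order.
#'
#' @param pair A [sibling_pair()].
#' @return List of `informative_call` objects (possibly empty).
#' @export
informative_loci <- function(pair) {
  stopifnot(inherits(pair, "sibling_pair"))
  if (length(pair$donor) == 0L)
    stop("pair ", pair$pair_id, " carries no genotypes")
  calls <- lapply(names(pair$donor), function(loc)
    classify_alleles(pair$donor[[loc]], pair$recipient[[loc]]))
  keep <- vapply(calls, `[[`, logical(1), "informative")
  calls <- calls[keep]
  if (length(calls) == 0L) return(calls)
  full <- vapply(calls, `[[`, logical(1), "fully_informative")
  n_rex <- vapply(calls, function(cl) length(cl$recipient_exclusive), numeric(1))
  calls[order(-full, -n_rex, seq_along(calls))]
}

#' Cohort informativeness table
#'
#' For each panel locus, counts the sibling pairs at which the locus is
#' informative, and groups loci as common (>= 25% of pairs), uncommon
#' (10-25%) or rare (< 10%).
#'
#' @param cohort List of [sibling_pair()] objects.
#' @param panel Named list of [str_locus()] (default [default_panel()]).
#' @return `data.frame` with columns `locus`, `n_informative`, `n_pairs`,
#'   `fraction`, `percent`, `category`, one row per panel locus in panel
#'   order.
#' @export
informativeness_table <- function(cohort, panel = default_panel()) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, logical(1), "sibling_pair")))
  n_pairs <- length(cohort)
  rows <- lapply(names(panel), function(loc) {
    inf <- vapply(cohort, function(pair) {
      if (!loc %in% names(pair$donor))
        stop("pair ", pair$pair_id, " is not typed at panel locus ", loc)
      classify_alleles(pair$donor[[loc]], pair$recipient[[loc]])$informative
    }, logical(1))
    n_inf <- sum(inf)
    frac <- n_inf / n_pairs
    data.frame(
      locus = loc, n_informative = n_inf, n_pairs = n_pairs,
      fraction = frac, percent = 100 * frac,
      category = if (frac >= 0.25) "common" else if (frac >= 0.10) "uncommon" else "rare",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-pair informative-locus counts
#'
#' @param cohort List of [sibling_pair()] objects.
#' @return Named integer vector, one count per pair.
#' @export
informative_counts <- function(cohort) {
  vapply(cohort, function(pair) length(informative_loci(pair)), integer(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort, `[[`, character(1), "pair_id"))
}

#' Read a genotype table
#'
#' Reads a tab-separated genotype table with columns `pair_id`, `role`
#' (`donor` or `recipient`), `locus`, `allele1`, `allele2`. Lines starting
#' with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return List of [sibling_pair()] objects, in file order of first
#'   appearance.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pair_id", "role", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient'")
  pair_ids <- unique(df$pair_id)
  lapply(pair_ids, function(pid) {
    sub <- df[df$pair_id == pid, ]
    gset <- function(role) {
      rs <- sub[sub$role == role, ]
      lapply(seq_len(nrow(rs)), function(i)
        genotype(rs$locus[i], c(rs$allele1[i], rs$allele2[i])))
    }
    sibling_pair(as.character(pid), gset("donor"), gset("recipient"))
  })
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()].
#'
#' @param cohort List of [sibling_pair()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(pair) {
    do.call(rbind, lapply(c("donor", "recipient"), function(role) {
      gs <- pair[[role]]
      data.frame(
        pair_id = pair$pair_id, role = role,
        locus = vapply(gs, `[[`, character(1), "locus"),
        allele1 = vapply(gs, function(g) g$alleles[1], numeric(1)),
        allele2 = vapply(gs, function(g) g$alleles[2], numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an informativeness table as TSV
#'
#' Columns: locus, informative (as `n/N`), percent, category.
#'
#' @param tab Output of [informativeness_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_informativeness <- function(tab, path) {
  out <- data.frame(
    locus = tab$locus,
    informative = sprintf("%d/%d", tab$n_informative, tab$n_pairs),
    percent = sprintf("%.1f", tab$percent),
    category = tab$category,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
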