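#' STR locus definition
#'
#' Describes one short tandem repeat (STR) locus: its repeat-unit length, the
#' range of allele repeat counts seen in practice, and a linear map from
#' repeat count to amplicon fragment size,
#' `size_bp = offset_bp + repeat_unit_bp * repeat_count`.
#'
#' @param name Locus identifier, e.g. `"D5S818"`. Must be non-empty.
#' @param repeat_unit_bp Integer length of the repeat motif in bp (2-6).
#' @param allele_range Integer vector `c(min, max)` of repeat counts.
#' @param offset_bp Flanking (non-repeat) length of the amplicon in bp, used
#'   to convert repeat counts to fragment sizes.
#'
#' @return An object of class `str_locus`: a list with fields `name`,
#'   `repeat_unit_bp`, `allele_range`, `offset_bp`, and the derived
#'   `size_range_bp`.
#' @examples
#' loc <- str_locus("D5S818", 4L, c(7L, 16L), offset_bp = 106)
#' allele_size_bp(loc, 12)
#' @export
str_locus <- function(name, repeat_unit_bp, allele_range, offset_bp) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  repeat_unit_bp <- as.integer(repeat_unit_bp)
  if (repeat_unit_bp < 2L || repeat_unit_bp > 6L)
    stop("repeat_unit_bp must be in [2, 6], got ", repeat_unit_bp)
  allele_range <- as.integer(allele_range)
  stopifnot(length(allele_range) == 2L)
  if (allele_range[1] >= allele_range[2])
    stop("allele_range must satisfy min < max for locus ", name)
  structure(
    list(
      name = name,
      repeat_unit_bp = repeat_unit_bp,
      allele_range = allele_range,
      offset_bp = as.numeric(offset_bp),
      size_range_bp = offset_bp + repeat_unit_bp * allele_range
    ),
    class = "str_locus"
  )
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("<str_locus> %s: %d-bp repeat, alleles %d-%d (%g-%g bp)\n",
              x$name, x$repeat_unit_bp, x$allele_range[1], x$allele_range[2],
              x$size_range_bp[1], x$size_range_bp[2]))
  invisible(x)
}

#' Fragment size of an allele at a locus
#'
#' @param locus An [str_locus()].
#' @param allele Repeat count(s).
#' @return Fragment size(s) in bp.
#' @export
allele_size_bp <- function(locus, allele) {
  stopifnot(inherits(locus, "str_locus"))
  locus$offset_bp + locus$repeat_unit_bp * as.numeric(allele)
}

#' Default autosomal STR panel
#'
#' The ten autosomal STR loci used for sibling donor/recipient typing, in
#' panel order. Allele ranges are repeat counts; fragment sizes follow the
#' per-locus linear size model and are chosen so that all amplicons fall in a
#' 110-360 bp electrophoresis window.
#'
#' @return A named list of [str_locus()] objects.
#' @examples
#' names(default_panel())
#' @export
default_panel <- function() {
  loci <- list(
    str_locus("D5S818",     4L, c(7L, 16L),  offset_bp = 106),
    str_locus("D3S1358",    4L, c(12L, 20L), offset_bp = 69),
    str_locus("D7S820",     4L, c(6L, 14L),  offset_bp = 180),
    str_locus("D8S1179",    4L, c(8L, 19L),  offset_bp = 91),
    str_locus("FGA",        4L, c(18L, 30L), offset_bp = 140),
    str_locus("TH01",       4L, c(5L, 11L),  offset_bp = 154),
    str_locus("TPOX",       4L, c(6L, 13L),  offset_bp = 190),
    str_locus("D13S317",    4L, c(8L, 15L),  offset_bp = 140),
    str_locus("D18S51-R",   4L, c(7L, 27L),  offset_bp = 245),
    str_locus("D21S1411-F", 4L, c(24L, 38L), offset_bp = 150)
  )
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(names(loci))) stop("panel locus names must be unique")
  loci
}

panel_locus <- function(panel, name) {
  if (!name %in% names(panel))
    stop("locus '", name, "' is not in the panel (",
         paste(names(panel), collapse = ", "), ")")
  panel[[name]]
}
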