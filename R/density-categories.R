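#' BI-RADS density categories and their ordinal coding
#'
#' Breast density is reported on the four-level ordinal BI-RADS scale:
#' a (almost entirely fatty), b (scattered fibroglandular), c (heterogeneously
#' dense), d (extremely dense). Internally the package works with integer
#' codes 0--3 so that longitudinal changes can be expressed as signed
#' differences; labels appear only at I/O boundaries. The binary context
#' collapses the scale into non-dense (a, b) versus dense (c, d), the split
#' that drives supplemental-screening recommendations.
#'
#' @name density-scale
NULL

#' @rdname density-scale
#' @format `density_levels` is the character vector `c("a","b","c","d")` in
#'   ordinal order.
#' @export
density_levels <- c("a", "b", "c", "d")

#' @rdname density-scale
#' @param x A character vector of BI-RADS labels (`"a"`--`"d"`,
#'   case-insensitive) or an integer vector already coded 0--3.
#' @return `density_code()` returns an integer vector in 0--3 with `NA` for
#'   unrecognised labels.
#' @examples
#' density_code(c("a", "B", "d"))
#' density_label(c(0L, 3L))
#' binarize_density(c(0L, 1L, 2L, 3L))
#' @export
density_code <- function(x) {
  if (is.numeric(x)) {
    code <- as.integer(x)
    code[!code %in% 0:3] <- NA_integer_
    return(code)
  }
  match(tolower(trimws(as.character(x))), density_levels) - 1L
}

#' @rdname density-scale
#' @param code An integer vector of codes 0--3.
#' @return `density_label()` returns the corresponding `"a"`--`"d"` labels.
#' @export
density_label <- function(code) {
  density_levels[as.integer(code) + 1L]
}

#' @rdname density-scale
#' @return `binarize_density()` maps codes elementwise to 0 (non-dense:
#'   a, b) or 1 (dense: c, d), preserving length and `NA`s.
#' @export
binarize_density <- function(x) {
  code <- density_code(x)
  as.integer(code >= 2L)
}
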