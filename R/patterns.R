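#' Longitudinal density-pattern labels
#'
#' A woman's ordered sequence of ordinal density assessments is summarised by
#' one of four longitudinal patterns, driven by the signs of consecutive-pair
#' differences:
#'
#' * **constant** — no change anywhere (all assessments equal);
#' * **ascending** — at least one increase and no decrease (plateaus allowed);
#' * **descending** — at least one decrease and no increase;
#' * **bi-directional** — both an increase and a decrease somewhere.
#'
#' The four labels partition all sequences of length >= 3. Over a ~5-year
#' screening window true density changes slowly and mostly downward, so
#' bi-directional patterns are physiologically implausible and act as a
#' signature of assessment variability. Consecutive-pair differences (rather
#' than first-versus-last comparison) are used because bi-directionality is
#' invisible to the endpoints.
#'
#' @name pattern-taxonomy
NULL

pattern_levels <- c("constant", "ascending", "descending", "bi-directional")

#' Classify one ordinal sequence into a longitudinal pattern
#'
#' @param seq An ordered vector (length >= 3) of ordinal codes, e.g. density
#'   codes 0--3 or binary codes 0/1.
#' @return A single factor level among `constant`, `ascending`, `descending`,
#'   `bi-directional`.
#' @examples
#' classify_pattern(c(2, 2, 2)) # c,c,c -> constant
#' classify_pattern(c(1, 2, 3)) # b,c,d -> ascending
#' classify_pattern(c(1, 0, 1)) # b,a,b -> bi-directional
#' @export
classify_pattern <- function(seq) {
  seq <- as.numeric(seq)
  if (length(seq) < 3 || anyNA(seq)) {
    abort("pattern classification needs a complete sequence of length >= 3")
  }
  d <- diff(seq)
  has_up <- any(d > 0)
  has_down <- any(d < 0)
  label <- if (!has_up && !has_down) {
    "constant"
  } else if (has_up && !has_down) {
    "ascending"
  } else if (has_down && !has_up) {
    "descending"
  } else {
    "bi-directional"
  }
  factor(label, levels = pattern_levels)
}

rater_column <- function(rater = c("ai", "reader")) {
  rater <- match.arg(rater)
  paste0(rater, "_density")
}

context_transform <- function(context = c("four_category", "binary")) {
  context <- match.arg(context)
  if (context == "binary") binarize_density else density_code
}

#' Per-woman longitudinal pattern labels
#'
#' Classifies every woman's density sequence for one rater in one context.
#' Rows within a woman are taken in `exam_date` order.
#'
#' @param cohort A cohort tibble.
#' @param rater `"ai"` or `"reader"`.
#' @param context `"four_category"` (BI-RADS a--d) or `"binary"`
#'   (non-dense vs dense). Binary patterns are computed on the binarized
#'   sequence itself, not read off the four-category label: the two contexts
#'   are separate analyses.
#' @return A tibble with one row per woman: `woman_id`, `pattern`.
#' @export
classify_patterns <- function(cohort, rater = c("ai", "reader"),
                              context = c("four_category", "binary")) {
  col <- rater_column(rater)
  f <- context_transform(context)
  cohort |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$woman_id, .data$exam_date) |>
    dplyr::summarise(
      pattern = classify_pattern(f(.data[[col]])),
      .by = "woman_id"
    )
}

#' Pattern frequency table for one rater
#'
#' @inheritParams classify_patterns
#' @return A tibble with columns `pattern`, `n`, `pct` (percentage of women,
#'   rounded to one decimal as in standard reporting). Counts sum to the
#'   number of women.
#' @export
pattern_table <- function(cohort, rater = c("ai", "reader"),
                          context = c("four_category", "binary")) {
  if (nrow(cohort) == 0) abort("cannot tabulate patterns for an empty cohort")
  labels <- classify_patterns(cohort, rater, context)
  counts <- table(labels$pattern)
  tibble::tibble(
    pattern = factor(pattern_levels, levels = pattern_levels),
    n = as.integer(counts[pattern_levels]),
    pct = round(100 * as.integer(counts[pattern_levels]) / nrow(labels), 1)
  )
}

#' Paired (AI x radiologist) pattern cross-tabulation
#'
#' Cross-tabulates per-woman pattern labels of the two raters; the marginals
#' equal the two single-rater [pattern_table()] outputs.
#'
#' @inheritParams classify_patterns
#' @return A tibble in long form with columns `ai_pattern`, `reader_pattern`,
#'   `n`; entries sum to the number of women. The 4x4 count matrix (rows =
#'   AI) is attached as attribute `"matrix"`.
#' @export
paired_pattern_table <- function(cohort,
                                 context = c("four_category", "binary")) {
  if (nrow(cohort) == 0) abort("cannot tabulate patterns for an empty cohort")
  ai <- classify_patterns(cohort, "ai", context)
  rd <- classify_patterns(cohort, "reader", context)
  paired <- dplyr::inner_join(
    dplyr::rename(ai, ai_pattern = "pattern"),
    dplyr::rename(rd, reader_pattern = "pattern"),
    by = "woman_id"
  )
  m <- table(ai = paired$ai_pattern, reader = paired$reader_pattern)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- c("ai_pattern", "reader_pattern", "n")
  out$ai_pattern <- factor(out$ai_pattern, levels = pattern_levels)
  out$reader_pattern <- factor(out$reader_pattern, levels = pattern_levels)
  out$n <- as.integer(out$n)
  out <- dplyr::arrange(out, .data$ai_pattern, .data$reader_pattern)
  attr(out, "matrix") <- unclass(m)
  attr(out, "n_women") <- nrow(paired)
  out
}

#' First-to-last density transition table for one rater
#'
#' Counts women by (first-exam category, last-exam category) for one rater —
#' the flow table behind Sankey plots of density change across the screening
#' window. Intermediate exams do not enter.
#'
#' @inheritParams classify_patterns
#' @return A tibble with columns `first_density`, `last_density` (labels
#'   `a`--`d`), `n`; entries sum to the number of women.
#' @export
transition_table <- function(cohort, rater = c("ai", "reader")) {
  if (nrow(cohort) == 0) abort("cannot tabulate transitions for an empty cohort")
  col <- rater_column(rater)
  ends <- cohort |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$woman_id, .data$exam_date) |>
    dplyr::summarise(
      first = dplyr::first(.data[[col]]),
      last = dplyr::last(.data[[col]]),
      .by = "woman_id"
    )
  m <- table(
    factor(density_label(ends$first), levels = density_levels),
    factor(density_label(ends$last), levels = density_levels)
  )
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- c("first_density", "last_density", "n")
  out$n <- as.integer(out$n)
  dplyr::arrange(out, .data$first_density, .data$last_density)
}

#' Export a transition table as a Sankey-ready CSV
#'
#' Writes the three-column `source_category, target_category, count` layout
#' consumed by standard Sankey plotters.
#'
#' @param transitions Output of [transition_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sankey_csv <- function(transitions, path) {
  out <- tibble::tibble(
    source_category = transitions$first_density,
    target_category = transitions$last_density,
    count = transitions$n
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
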