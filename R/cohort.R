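#' Screening-cohort tables
#'
#' A cohort is a tibble with one row per screening examination and one block
#' of consecutive rows per woman, carrying both raters' BI-RADS density
#' assessments for the same examination. The canonical columns are:
#'
#' * `woman_id` — opaque woman identifier (character).
#' * `exam_date` — ISO-8601 calendar date, or an integer exam index; must be
#'   strictly increasing within a woman (same-date duplicates are invalid:
#'   screening exams are annual, and the handling of technical recalls on a
#'   shared date is not defined, so they are flagged rather than guessed).
#' * `reader_id` — interpreting radiologist identifier (character).
#' * `reader_fellowship` — logical; fellowship-trained radiologist.
#' * `reader_density`, `ai_density` — integer density codes 0--3
#'   (see [density_code()]); CSV files carry the labels `a`--`d`.
#' * `age_years` — age at the examination, in `[18, 110]`.
#' * `bmi` — optional body-mass index in kg/m^2, in `(10, 80)` when present.
#' * `fat_measure` — optional image-based breast-fat fraction in `[0, 1]`.
#' * `thickness_mm` — optional compressed breast thickness in mm, positive.
#'
#' Only women with at least three valid examinations are retained (the
#' longitudinal-pattern taxonomy needs at least two consecutive changes);
#' excluded women and malformed rows are tallied in the cohort's provenance
#' attribute, retrievable with [cohort_provenance()].
#'
#' @name density_cohort
NULL

cohort_columns <- c(
  "woman_id", "exam_date", "reader_id", "reader_fellowship",
  "reader_density", "ai_density", "age_years", "bmi",
  "fat_measure", "thickness_mm"
)

new_density_cohort <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  class(x) <- c("density_cohort", class(x))
  attr(x, "provenance") <- provenance
  x
}

#' Retrieve a cohort's provenance tallies
#'
#' @param cohort A cohort tibble produced by [read_cohort()],
#'   [as_density_cohort()] or [simulate_cohort()].
#' @return A list with the source path (if any), input row and woman counts,
#'   and exclusion tallies (`n_rows_malformed`, `n_women_excluded_short`).
#' @export
cohort_provenance <- function(cohort) {
  attr(cohort, "provenance")
}

# Row-level validity; returns a logical keep-vector and per-rule tallies.
validate_exam_rows <- function(df) {
  ok_reader <- !is.na(df$reader_density) & df$reader_density %in% 0:3
  ok_ai <- !is.na(df$ai_density) & df$ai_density %in% 0:3
  ok_age <- !is.na(df$age_years) & df$age_years >= 18 & df$age_years <= 110
  ok_bmi <- is.na(df$bmi) | (df$bmi > 10 & df$bmi < 80)
  ok_fat <- is.na(df$fat_measure) | (df$fat_measure >= 0 & df$fat_measure <= 1)
  ok_thk <- is.na(df$thickness_mm) | df$thickness_mm > 0
  ok_ids <- !is.na(df$woman_id) & !is.na(df$exam_date)
  dup <- duplicated(df[c("woman_id", "exam_date")]) |
    duplicated(df[c("woman_id", "exam_date")], fromLast = TRUE)
  keep <- ok_reader & ok_ai & ok_age & ok_bmi & ok_fat & ok_thk & ok_ids & !dup
  list(
    keep = keep,
    tallies = c(
      bad_density = sum(!(ok_reader & ok_ai)),
      bad_age = sum(ok_reader & ok_ai & !ok_age),
      bad_optional = sum(ok_reader & ok_ai & ok_age & !(ok_bmi & ok_fat & ok_thk)),
      bad_id = sum(!ok_ids),
      duplicate_date = sum(dup & ok_ids)
    )
  )
}

#' Validate a per-examination table and assemble a cohort
#'
#' Applies the row-level validity rules, sorts each woman's examinations by
#' date, drops women with fewer than three valid examinations, and attaches
#' provenance tallies so that included women plus every exclusion reconcile
#' with the input.
#'
#' @param data A data frame with the canonical columns (see
#'   [density_cohort]); density columns may be `a`--`d` labels or 0--3 codes.
#' @param strict If `TRUE`, any malformed row aborts with an error; if
#'   `FALSE` (default) malformed rows are dropped and tallied.
#' @param source Optional source label recorded in provenance.
#' @return A `density_cohort` tibble sorted by woman and date.
#' @export
as_density_cohort <- function(data, strict = FALSE, source = NULL) {
  missing_cols <- setdiff(cohort_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- tibble::as_tibble(data)[cohort_columns]
  df$woman_id <- as.character(df$woman_id)
  df$reader_id <- as.character(df$reader_id)
  df$reader_fellowship <- as.logical(df$reader_fellowship)
  df$reader_density <- density_code(df$reader_density)
  df$ai_density <- density_code(df$ai_density)
  for (col in c("age_years", "bmi", "fat_measure", "thickness_mm")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  n_rows_input <- nrow(df)
  n_women_input <- dplyr::n_distinct(df$woman_id[!is.na(df$woman_id)])
  chk <- validate_exam_rows(df)
  if (strict && any(!chk$keep)) {
    abort(sprintf(
      "%d malformed row(s) in strict mode (first at input row %d)",
      sum(!chk$keep), which(!chk$keep)[1]
    ))
  }
  df <- df[chk$keep, ]
  df <- dplyr::arrange(df, .data$woman_id, .data$exam_date)

  n_exams <- table(df$woman_id)
  short_women <- names(n_exams)[n_exams < 3]
  df <- df[!df$woman_id %in% short_women, ]

  prov <- list(
    source = source,
    n_rows_input = n_rows_input,
    n_rows_malformed = sum(!chk$keep),
    row_tallies = as.list(chk$tallies),
    n_women_input = n_women_input,
    n_women_excluded_short = length(short_women),
    n_women = dplyr::n_distinct(df$woman_id),
    n_exams = nrow(df)
  )
  new_density_cohort(df, provenance = prov)
}

#' Read a per-examination cohort CSV
#'
#' Reads a UTF-8 CSV with header columns `woman_id, exam_date, reader_id,
#' reader_fellowship, reader_density, ai_density, age_years, bmi,
#' fat_measure, thickness_mm` (the last three may be blank), converts density
#' labels to ordinal codes, and assembles a validated cohort via
#' [as_density_cohort()].
#'
#' @param path Path to the CSV file.
#' @inheritParams as_density_cohort
#' @return A `density_cohort` tibble; see [cohort_provenance()] for the
#'   exclusion tallies.
#' @export
read_cohort <- function(path, strict = FALSE) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      woman_id = readr::col_character(),
      exam_date = readr::col_date(format = ""),
      reader_id = readr::col_character(),
      reader_fellowship = readr::col_integer(),
      reader_density = readr::col_character(),
      ai_density = readr::col_character(),
      age_years = readr::col_double(),
      bmi = readr::col_double(),
      fat_measure = readr::col_double(),
      thickness_mm = readr::col_double()
    ),
    progress = FALSE
  )
  as_density_cohort(df, strict = strict, source = path)
}

#' Write a cohort back to CSV (with optional provenance sidecar)
#'
#' Densities are written as `a`--`d` labels and `reader_fellowship` as 0/1,
#' matching the input format, so that `read_cohort(write_cohort(x))` is the
#' identity on valid cohorts.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param provenance_path Optional path for a JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, provenance_path = NULL) {
  out <- tibble::as_tibble(cohort)[intersect(cohort_columns, names(cohort))]
  out$reader_density <- density_label(out$reader_density)
  out$ai_density <- density_label(out$ai_density)
  out$reader_fellowship <- as.integer(out$reader_fellowship)
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(provenance_path)) {
    prov <- cohort_provenance(cohort) %||% list()
    jsonlite::write_json(prov, provenance_path, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Number of women in a cohort
#'
#' @param cohort A cohort tibble.
#' @return Integer count of distinct `woman_id`s.
#' @export
n_women <- function(cohort) {
  dplyr::n_distinct(cohort$woman_id)
}
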