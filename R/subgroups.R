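#' Clinically motivated subgroup filters
#'
#' The full-cohort comparison is re-run in four overlapping subgroups that
#' each suppress one source of apparent density change or rater variability:
#'
#' * **postmenopausal** — women strictly older than the age threshold
#'   (default 55 years) at their first examination: a menopause proxy, since
#'   density declines mostly before/around menopause;
#' * **stable_bmi** — women whose BMI changes by less than the relative
#'   threshold (default 5%) between every pair of consecutive examinations:
#'   suppresses weight-driven density change;
#' * **same_reader** — women whose examinations were all interpreted by one
#'   radiologist: removes inter-observer variability;
#' * **fellowship** — women whose examinations were all interpreted by
#'   fellowship-trained radiologists.
#'
#' Filters keep or drop whole women (never individual exams), are idempotent,
#' and commute, so each subgroup is a subset of the full cohort and subgroup
#' counts can never exceed full-cohort counts.
#'
#' @name subgroup-filters
NULL

woman_filter <- function(cohort, keep_women) {
  out <- tibble::as_tibble(cohort)
  out <- out[out$woman_id %in% keep_women, ]
  new_density_cohort(out, provenance = cohort_provenance(cohort))
}

#' @rdname subgroup-filters
#' @param cohort A cohort tibble.
#' @param age_threshold Age in years; women with first-exam age strictly
#'   greater than this are kept.
#' @return A filtered cohort tibble.
#' @export
filter_postmenopausal <- function(cohort, age_threshold = 55) {
  first_age <- cohort |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$woman_id, .data$exam_date) |>
    dplyr::summarise(age = dplyr::first(.data$age_years), .by = "woman_id")
  woman_filter(cohort, first_age$woman_id[first_age$age > age_threshold])
}

#' @rdname subgroup-filters
#' @param rel_threshold Maximum tolerated proportional BMI change between
#'   consecutive examinations (default 0.05, i.e. < 5%). The between-exam
#'   change is checked for every consecutive pair, not first-versus-last.
#' @param proxy Optional [fit_bmi_proxy()] model used to fill missing BMI
#'   from `fat_measure` and `thickness_mm` before filtering. Women still
#'   missing BMI on any exam are excluded.
#' @export
filter_stable_bmi <- function(cohort, rel_threshold = 0.05, proxy = NULL) {
  df <- tibble::as_tibble(cohort)
  if (!is.null(proxy)) {
    fill <- is.na(df$bmi) & !is.na(df$fat_measure) & !is.na(df$thickness_mm)
    df$bmi[fill] <- estimate_bmi(proxy, df$fat_measure[fill],
                                 df$thickness_mm[fill])
  }
  stable <- df |>
    dplyr::arrange(.data$woman_id, .data$exam_date) |>
    dplyr::summarise(
      stable = !anyNA(.data$bmi) &&
        (dplyr::n() < 2 ||
           all(abs(diff(.data$bmi)) / head(.data$bmi, -1) < rel_threshold)),
      .by = "woman_id"
    )
  woman_filter(cohort, stable$woman_id[stable$stable])
}

#' @rdname subgroup-filters
#' @export
filter_same_reader <- function(cohort) {
  readers <- cohort |>
    tibble::as_tibble() |>
    dplyr::summarise(one = dplyr::n_distinct(.data$reader_id) == 1,
                     .by = "woman_id")
  woman_filter(cohort, readers$woman_id[readers$one])
}

#' @rdname subgroup-filters
#' @export
filter_fellowship <- function(cohort) {
  fel <- cohort |>
    tibble::as_tibble() |>
    dplyr::summarise(all_fellow = all(as.logical(.data$reader_fellowship)),
                     .by = "woman_id")
  woman_filter(cohort, fel$woman_id[fel$all_fellow])
}

#' Split a cohort into the full cohort plus the four subgroups
#'
#' @inheritParams filter_postmenopausal
#' @inheritParams filter_stable_bmi
#' @return A named list of cohort tibbles: `full`, `postmenopausal`,
#'   `stable_bmi`, `same_reader`, `fellowship`. Subgroups overlap: a woman
#'   may appear in several.
#' @export
subgroup_cohorts <- function(cohort, age_threshold = 55, rel_threshold = 0.05,
                             proxy = NULL) {
  list(
    full = cohort,
    postmenopausal = filter_postmenopausal(cohort, age_threshold),
    stable_bmi = filter_stable_bmi(cohort, rel_threshold, proxy),
    same_reader = filter_same_reader(cohort),
    fellowship = filter_fellowship(cohort)
  )
}
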