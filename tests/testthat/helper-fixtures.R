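# In-code fixtures: tiny hand-built cohorts and an independent pattern oracle.

# One woman's exam block with both raters' density label sequences.
woman_rows <- function(id, reader_seq, ai_seq = reader_seq,
                       reader_id = "R01", fellowship = TRUE,
                       age0 = 50, bmi = NULL, start = as.Date("2016-01-05")) {
  k <- length(reader_seq)
  tibble::tibble(
    woman_id = id,
    exam_date = start + 365 * (seq_len(k) - 1),
    reader_id = rep_len(reader_id, k),
    reader_fellowship = rep_len(fellowship, k),
    reader_density = reader_seq,
    ai_density = ai_seq,
    age_years = age0 + seq_len(k) - 1,
    bmi = if (is.null(bmi)) NA_real_ else bmi,
    fat_measure = NA_real_,
    thickness_mm = NA_real_
  )
}

make_cohort <- function(...) {
  as_density_cohort(dplyr::bind_rows(...))
}

# Independent pattern oracle: compares the sequence with its sorted versions
# instead of walking consecutive differences.
oracle_pattern <- function(s) {
  if (all(s == s[1])) return("constant")
  if (identical(as.numeric(s), as.numeric(sort(s)))) return("ascending")
  if (identical(as.numeric(s), as.numeric(rev(sort(s))))) return("descending")
  "bi-directional"
}

# All length-k sequences over codes 0..(m-1), one per row.
all_sequences <- function(k, m) {
  as.matrix(expand.grid(rep(list(0:(m - 1)), k)))
}

small_sim <- function(n = 500, seed = 1, ...) {
  simulate_cohort(sim_config(n_women = n, seed = seed, ...))
}
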