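#' McNemar paired-proportion test
#'
#' Tests whether two raters assessing the same subjects differ in how often
#' they assign a binary trait (here: a given longitudinal pattern label).
#' Only discordant pairs carry information: `b` counts subjects where the AI
#' has the trait and the radiologist does not, `c` the reverse.
#'
#' Methods:
#' * `exact` — two-sided exact binomial: `p = min(1, 2 * P(X <= min(b, c)))`
#'   with `X ~ Binomial(b + c, 1/2)`;
#' * `chi2_cc` — continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)`
#'   on 1 df;
#' * `chi2` — uncorrected `(b - c)^2 / (b + c)`;
#' * `auto` (default) — exact when `b + c < 25`, else `chi2_cc`, the usual
#'   small-sample convention.
#'
#' With no discordant pairs (`b = c = 0`) the statistic is 0 and `p = 1`.
#'
#' @param ai_flag,reader_flag Logical vectors of equal length: the paired
#'   per-subject trait indicators for the two raters.
#' @param method One of `"auto"`, `"exact"`, `"chi2_cc"`, `"chi2"`.
#' @return An object of class `mcnemar_paired` with elements `b`, `c`,
#'   `statistic`, `p_value`, `method`, `n`. `tidy()` and `glance()` methods
#'   return one-row tibbles.
#' @examples
#' set.seed(1)
#' x <- runif(50) < 0.6
#' y <- runif(50) < 0.4
#' tidy(mcnemar_paired(x, y))
#' @export
mcnemar_paired <- function(ai_flag, reader_flag,
                           method = c("auto", "exact", "chi2_cc", "chi2")) {
  method <- match.arg(method)
  if (length(ai_flag) == 0 || length(ai_flag) != length(reader_flag)) {
    abort("paired flags must be non-empty vectors of equal length")
  }
  ai_flag <- as.logical(ai_flag)
  reader_flag <- as.logical(reader_flag)
  if (anyNA(ai_flag) || anyNA(reader_flag)) {
    abort("paired flags must not contain NA")
  }
  b <- sum(ai_flag & !reader_flag)
  cc <- sum(!ai_flag & reader_flag)
  if (method == "auto") method <- if (b + cc < 25) "exact" else "chi2_cc"

  if (b + cc == 0) {
    stat <- 0
    p <- 1
  } else if (method == "exact") {
    stat <- min(b, cc)
    p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  } else if (method == "chi2_cc") {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- (b - cc)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(b = b, c = cc, statistic = stat, p_value = p,
         method = method, n = length(ai_flag)),
    class = "mcnemar_paired"
  )
}

#' @export
print.mcnemar_paired <- function(x, ...) {
  cat("McNemar paired-proportion test (", x$method, ")\n", sep = "")
  cat(sprintf("  discordant pairs: b = %d, c = %d (n = %d)\n", x$b, x$c, x$n))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @rdname mcnemar_paired
#' @param x An `mcnemar_paired` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.mcnemar_paired <- function(x, ...) {
  tibble::tibble(
    b = x$b, c = x$c, statistic = x$statistic,
    p.value = x$p_value, method = x$method
  )
}

#' @rdname mcnemar_paired
#' @exportS3Method generics::glance
#' @export
glance.mcnemar_paired <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method, n = x$n)
}

#' Percentage arithmetic used in reports
#'
#' Report tables quote percentages rounded to one decimal, and headline
#' differences are differences of those rounded percentages (so 81.0 - 56.8
#' prints as 24.2 even where the unrounded difference is 24.3). These helpers
#' centralise that convention.
#'
#' @param count,total Non-negative counts.
#' @return `report_pct()`: `100 * count / total` rounded to one decimal.
#' @export
report_pct <- function(count, total) {
  round(100 * count / total, 1)
}

#' @rdname report_pct
#' @param ai_count,reader_count Women with the trait under each rater.
#' @param n Total women.
#' @return `proportion_difference()`: one-row tibble with `ai_pct`,
#'   `reader_pct` and `diff_pp = ai_pct - reader_pct` (difference of the
#'   rounded percentages, in percentage points).
#' @export
proportion_difference <- function(ai_count, reader_count, n) {
  ai_pct <- report_pct(ai_count, n)
  reader_pct <- report_pct(reader_count, n)
  tibble::tibble(
    n = n, ai_n = ai_count, reader_n = reader_count,
    ai_pct = ai_pct, reader_pct = reader_pct,
    diff_pp = round(ai_pct - reader_pct, 1)
  )
}

#' Compare the raters' frequency of one longitudinal pattern
#'
#' Builds the per-woman paired indicator (AI pattern equals `trait`,
#' radiologist pattern equals `trait`), runs [mcnemar_paired()] on it, and
#' reports both proportions and their difference using the rounded-percent
#' convention of [proportion_difference()].
#'
#' @inheritParams classify_patterns
#' @param trait One of `"constant"`, `"ascending"`, `"descending"`,
#'   `"bi-directional"`.
#' @param method McNemar method, passed to [mcnemar_paired()].
#' @return A one-row tibble: `trait`, `context`, `n`, `ai_n`, `reader_n`,
#'   `ai_pct`, `reader_pct`, `diff_pp`, `b`, `c`, `statistic`, `p_value`,
#'   `method`.
#' @export
compare_pattern_proportions <- function(cohort,
                                        context = c("four_category", "binary"),
                                        trait = pattern_levels,
                                        method = "auto") {
  context <- match.arg(context)
  trait <- match.arg(trait)
  if (nrow(cohort) == 0) abort("cannot compare proportions on an empty cohort")
  ai <- classify_patterns(cohort, "ai", context)
  rd <- classify_patterns(cohort, "reader", context)
  paired <- dplyr::inner_join(
    dplyr::rename(ai, ai_pattern = "pattern"),
    dplyr::rename(rd, reader_pattern = "pattern"),
    by = "woman_id"
  )
  ai_flag <- paired$ai_pattern == trait
  reader_flag <- paired$reader_pattern == trait
  test <- mcnemar_paired(ai_flag, reader_flag, method = method)
  dplyr::bind_cols(
    tibble::tibble(trait = trait, context = context),
    proportion_difference(sum(ai_flag), sum(reader_flag), nrow(paired)),
    tibble::tibble(b = test$b, c = test$c, statistic = test$statistic,
                   p_value = test$p_value, method = test$method)
  )
}

#' Stuart-Maxwell marginal-homogeneity test
#'
#' Tests whether two raters' category distributions are equal in a paired
#' k x k contingency table (here: exam-level BI-RADS categories from the AI
#' model and the radiologist for the same examinations). The statistic is
#' the quadratic form `d' V^{-1} d` on the first k-1 marginal differences
#' `d_i = n_{i.} - n_{.i}`, with `V_ii = n_{i.} + n_{.i} - 2 n_{ii}` and
#' `V_ij = -(n_{ij} + n_{ji})`, referred to chi-square on k-1 df. For k = 2
#' it reduces exactly to the McNemar chi-square without continuity
#' correction.
#'
#' @param ai_cat,reader_cat Paired category vectors (factors or codes) of
#'   equal length; categories with no observations under either rater are
#'   dropped.
#' @return An object of class `stuart_maxwell` with `statistic`, `df`,
#'   `p_value`, and the underlying `table`; `tidy()`/`glance()` methods
#'   return one-row tibbles.
#' @export
marginal_homogeneity <- function(ai_cat, reader_cat) {
  if (length(ai_cat) == 0 || length(ai_cat) != length(reader_cat)) {
    abort("paired categories must be non-empty vectors of equal length")
  }
  levels_all <- sort(unique(c(as.character(ai_cat), as.character(reader_cat))))
  if (length(levels_all) < 2) {
    abort("marginal homogeneity needs at least 2 categories present")
  }
  tab <- table(
    factor(as.character(ai_cat), levels = levels_all),
    factor(as.character(reader_cat), levels = levels_all)
  )
  k <- length(levels_all)
  d <- rowSums(tab) - colSums(tab)
  V <- -(tab + t(tab))
  diag(V) <- rowSums(tab) + colSums(tab) - 2 * diag(tab)
  idx <- seq_len(k - 1)
  Vsub <- matrix(as.numeric(V[idx, idx]), k - 1, k - 1)
  dsub <- as.numeric(d[idx])
  if (all(dsub == 0)) {
    # perfectly homogeneous marginals (e.g. full concordance): no evidence
    stat <- 0
  } else {
    sv <- svd(Vsub)
    pos <- sv$d > max(sv$d) * 1e-12
    u_pos <- sv$u[, pos, drop = FALSE]
    proj <- u_pos %*% (t(u_pos) %*% dsub)
    if (!any(pos) || max(abs(proj - dsub)) > 1e-8 * max(abs(dsub))) {
      abort(paste0(
        "singular covariance in marginal-homogeneity test ",
        "(degenerate table concentrating all mass in too few cells)"
      ))
    }
    # Moore-Penrose quadratic form d' V^- d
    stat <- as.numeric(crossprod(dsub, sv$v[, pos, drop = FALSE] %*%
                                   ((t(u_pos) %*% dsub) / sv$d[pos])))
  }
  structure(
    list(statistic = stat, df = k - 1,
         p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
         method = "stuart_maxwell", table = tab, n = length(ai_cat)),
    class = "stuart_maxwell"
  )
}

#' @export
print.stuart_maxwell <- function(x, ...) {
  cat("Stuart-Maxwell marginal-homogeneity test\n")
  cat(sprintf("  chi-square = %.4g, df = %d, p = %.4g (n = %d pairs)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' @rdname marginal_homogeneity
#' @param x A `stuart_maxwell` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.stuart_maxwell <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p.value = x$p_value, method = x$method)
}

#' @rdname marginal_homogeneity
#' @exportS3Method generics::glance
#' @export
glance.stuart_maxwell <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p.value = x$p_value, method = x$method, n = x$n)
}

#' Marginal homogeneity of exam-level density distributions
#'
#' Convenience wrapper applying [marginal_homogeneity()] to all paired
#' exam-level density assessments of a cohort — the paired analogue of
#' comparing the two raters' overall category distributions.
#'
#' @inheritParams classify_patterns
#' @return A `stuart_maxwell` object.
#' @export
density_marginal_homogeneity <- function(cohort,
                                         context = c("four_category", "binary")) {
  f <- context_transform(context)
  marginal_homogeneity(f(cohort$ai_density), f(cohort$reader_density))
}
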