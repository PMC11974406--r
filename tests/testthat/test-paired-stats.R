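make_flags <- function(b, c, concordant_yes = 0, concordant_no = 0) {
  list(
    ai = c(rep(TRUE, b), rep(FALSE, c), rep(TRUE, concordant_yes),
           rep(FALSE, concordant_no)),
    reader = c(rep(FALSE, b), rep(TRUE, c), rep(TRUE, concordant_yes),
               rep(FALSE, concordant_no))
  )
}

test_that("exact McNemar p-values match the binomial tail", {
  f <- make_flags(1, 9)
  res <- mcnemar_paired(f$ai, f$reader, method = "exact")
  # brute-force two-sided binomial tail: 2 * sum_{k<=1} C(10,k) / 2^10
  brute <- 2 * sum(choose(10, 0:1)) / 2^10
  expect_equal(res$p_value, brute)
  expect_equal(res$p_value, 0.021484375)

  sym <- mcnemar_paired(make_flags(5, 5)$ai, make_flags(5, 5)$reader,
                        method = "exact")
  expect_equal(sym$p_value, 1)

  none <- mcnemar_paired(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(none$p_value, 1)
  expect_equal(none$statistic, 0)
})

test_that("chi-square variants agree with the base-R reference", {
  f <- make_flags(12, 30, concordant_yes = 40, concordant_no = 18)
  tab <- table(f$ai, f$reader)
  cc <- mcnemar_paired(f$ai, f$reader, method = "chi2_cc")
  ref_cc <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(cc$statistic, unname(ref_cc$statistic))
  expect_equal(cc$p_value, ref_cc$p.value)
  plain <- mcnemar_paired(f$ai, f$reader, method = "chi2")
  ref <- stats::mcnemar.test(tab, correct = FALSE)
  expect_equal(plain$statistic, unname(ref$statistic))
  # auto switches from exact to corrected chi-square at b + c = 25
  expect_equal(mcnemar_paired(make_flags(10, 14)$ai,
                              make_flags(10, 14)$reader)$method, "exact")
  expect_equal(mcnemar_paired(make_flags(10, 15)$ai,
                              make_flags(10, 15)$reader)$method, "chi2_cc")
})

test_that("exact p depends only on the discordant counts and swaps cleanly", {
  f1 <- make_flags(3, 8)
  f2 <- make_flags(3, 8, concordant_yes = 100, concordant_no = 57)
  p1 <- mcnemar_paired(f1$ai, f1$reader, method = "exact")$p_value
  p2 <- mcnemar_paired(f2$ai, f2$reader, method = "exact")$p_value
  expect_equal(p1, p2)
  # exchanging raters leaves p unchanged
  swapped <- mcnemar_paired(f2$reader, f2$ai, method = "exact")
  expect_equal(swapped$p_value, p2)
  expect_equal(swapped$b, 8)
  expect_equal(swapped$c, 3)
})

test_that("proportion differences follow the rounded-percent convention", {
  # full-cohort constant counts: 81.0% vs 56.8% prints a 24.2-point gap
  row <- proportion_difference(49575, 34736, 61177)
  expect_equal(row$ai_pct, 81.0)
  expect_equal(row$reader_pct, 56.8)
  expect_equal(row$diff_pp, 24.2)
  # the unrounded difference is 24.3 - the convention matters
  expect_equal(round(100 * (49575 - 34736) / 61177, 1), 24.3)
})

test_that("compare_pattern_proportions wires flags, counts and McNemar together", {
  agree <- make_cohort(woman_rows("W1", c("a", "b", "c")),
                       woman_rows("W2", c("d", "d", "d")),
                       woman_rows("W3", c("c", "b", "b")))
  res <- compare_pattern_proportions(agree, "four_category", "constant")
  expect_equal(res$diff_pp, 0)
  expect_equal(res$p_value, 1)

  co <- make_cohort(
    woman_rows("W1", c("b", "c", "b"), c("b", "b", "b")),
    woman_rows("W2", c("a", "b", "a"), c("a", "a", "a")),
    woman_rows("W3", c("c", "c", "c"), c("c", "c", "c"))
  )
  res2 <- compare_pattern_proportions(co, "four_category", "constant",
                                      method = "exact")
  expect_equal(res2$ai_n, 3)
  expect_equal(res2$reader_n, 1)
  expect_equal(res2$b, 2)
  expect_equal(res2$c, 0)
  expect_equal(res2$diff_pp, 100 - 33.3)
})

test_that("Stuart-Maxwell reduces to uncorrected McNemar for two categories", {
  ai <- c(rep("x", 1), rep("y", 9), rep("x", 20), rep("y", 15))
  rd <- c(rep("y", 1), rep("x", 9), rep("x", 20), rep("y", 15))
  sm <- marginal_homogeneity(ai, rd)
  expect_equal(sm$df, 1)
  expect_equal(sm$statistic, (1 - 9)^2 / (1 + 9)) # 6.4
  ref <- stats::mcnemar.test(table(ai, rd), correct = FALSE)
  expect_equal(sm$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(sm$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Stuart-Maxwell handles concordance, degeneracy and 4x4 tables", {
  conc <- marginal_homogeneity(rep(c("a", "b", "c"), 10), rep(c("a", "b", "c"), 10))
  expect_equal(conc$statistic, 0)
  expect_equal(conc$p_value, 1)
  expect_equal(conc$df, 2)

  expect_error(marginal_homogeneity(rep("a", 5), rep("a", 5)),
               "at least 2 categories")
  # all mass on one discordant pattern in a 3-level table -> singular
  expect_error(marginal_homogeneity(rep(c("a", "b", "c"), c(5, 0, 0)),
                                    rep("a", 5)),
               "singular|at least 2")

  # shifted marginals at scale: strongly significant
  co <- simulate_cohort(sim_config(n_women = 4000, seed = 5))
  sm <- density_marginal_homogeneity(co, "four_category")
  expect_equal(sm$df, 3)
  expect_lt(sm$p_value, 0.001)
  expect_gte(sm$statistic, 0)
})
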