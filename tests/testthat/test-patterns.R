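test_that("worked examples classify as expected", {
  expect_equal(as.character(classify_pattern(c(2, 2, 2))), "constant")
  expect_equal(as.character(classify_pattern(c(1, 2, 3))), "ascending")
  expect_equal(as.character(classify_pattern(c(1, 0, 1))), "bi-directional")
  expect_equal(as.character(classify_pattern(c(3, 2, 2, 0))), "descending")
  # plateaus inside a monotone run do not break the run
  expect_equal(as.character(classify_pattern(c(1, 1, 2))), "ascending")
  expect_error(classify_pattern(c(1, 2)), "length >= 3")
})

test_that("classifier matches the enumeration oracle on all short sequences", {
  for (cfg in list(c(k = 3, m = 4), c(k = 4, m = 4), c(k = 3, m = 2))) {
    seqs <- all_sequences(cfg[["k"]], cfg[["m"]])
    got <- apply(seqs, 1, function(s) as.character(classify_pattern(s)))
    want <- apply(seqs, 1, oracle_pattern)
    expect_identical(got, want)
  }
  # frozen marginal counts over all 4^3 quaternary and 2^3 binary sequences
  q <- apply(all_sequences(3, 4), 1, function(s) as.character(classify_pattern(s)))
  expect_equal(as.integer(table(q)[c("constant", "ascending", "descending",
                                     "bi-directional")]),
               c(4L, 16L, 16L, 28L))
  b <- apply(all_sequences(3, 2), 1, function(s) as.character(classify_pattern(s)))
  expect_equal(as.integer(table(b)[c("constant", "ascending", "descending",
                                     "bi-directional")]),
               c(2L, 2L, 2L, 2L))
})

test_that("classification is a partition with reversal antisymmetry", {
  set.seed(42)
  swap <- c(constant = "constant", ascending = "descending",
            descending = "ascending", "bi-directional" = "bi-directional")
  for (i in 1:200) {
    s <- sample(0:3, sample(3:6, 1), replace = TRUE)
    lab <- as.character(classify_pattern(s))
    expect_true(lab %in% c("constant", "ascending", "descending",
                           "bi-directional"))
    expect_equal(as.character(classify_pattern(rev(s))), unname(swap[lab]))
    # monotone-map stability under binarization
    blab <- as.character(classify_pattern(binarize_density(s)))
    if (lab == "constant") expect_equal(blab, "constant")
    if (lab == "ascending") expect_true(blab %in% c("constant", "ascending"))
    if (lab == "descending") expect_true(blab %in% c("constant", "descending"))
  }
})

test_that("pattern tables count every woman exactly once", {
  co <- make_cohort(
    woman_rows("W1", c("b", "b", "b")),
    woman_rows("W2", c("a", "a", "a"), c("a", "b", "a")),
    woman_rows("W3", c("c", "c", "c", "c"))
  )
  tab <- pattern_table(co, "reader", "four_category")
  expect_equal(tab$n, c(3L, 0L, 0L, 0L))
  expect_equal(sum(tab$n), n_women(co))
  tab_ai <- pattern_table(co, "ai", "four_category")
  expect_equal(tab_ai$n[tab_ai$pattern == "bi-directional"], 1L)
  expect_error(pattern_table(co[0, ], "ai"), "empty")
})

test_that("simulated pattern tables equal a naive per-woman recount", {
  co <- small_sim(n = 300, seed = 7)
  for (rater in c("ai", "reader")) {
    for (ctx in c("four_category", "binary")) {
      tab <- pattern_table(co, rater, ctx)
      col <- paste0(rater, "_density")
      recount <- table(factor(vapply(
        split(seq_len(nrow(co)), co$woman_id),
        function(ix) {
          rows <- co[ix, ][order(co$exam_date[ix]), ]
          s <- rows[[col]]
          if (ctx == "binary") s <- binarize_density(s)
          oracle_pattern(s)
        }, ""
      ), levels = levels(tab$pattern)))
      expect_equal(tab$n, unname(as.integer(recount)))
    }
  }
})

test_that("paired pattern tables reconcile with single-rater marginals", {
  co <- small_sim(n = 300, seed = 8)
  for (ctx in c("four_category", "binary")) {
    paired <- paired_pattern_table(co, ctx)
    expect_equal(sum(paired$n), n_women(co))
    m <- attr(paired, "matrix")
    expect_equal(unname(rowSums(m)), pattern_table(co, "ai", ctx)$n)
    expect_equal(unname(colSums(m)), pattern_table(co, "reader", ctx)$n)
  }
  # perfect agreement -> diagonal; forced disagreement -> one off-diagonal cell
  agree <- make_cohort(woman_rows("W1", c("a", "b", "c")),
                       woman_rows("W2", c("d", "d", "d")))
  m <- attr(paired_pattern_table(agree, "four_category"), "matrix")
  expect_equal(sum(m[row(m) != col(m)]), 0)
  off <- make_cohort(
    woman_rows("W1", c("a", "b", "c"), c("b", "b", "b")),
    woman_rows("W2", c("a", "a", "b"), c("c", "c", "c"))
  )
  mo <- attr(paired_pattern_table(off, "four_category"), "matrix")
  expect_equal(mo["constant", "ascending"], 2)
  expect_equal(sum(mo), 2)
})

test_that("transition tables count first-to-last category moves", {
  co <- make_cohort(
    woman_rows("W1", c("b", "c", "d")),
    woman_rows("W2", c("a", "a", "a"))
  )
  tr <- transition_table(co, "reader")
  expect_equal(sum(tr$n), 2)
  expect_equal(tr$n[tr$first_density == "b" & tr$last_density == "d"], 1L)
  expect_equal(tr$n[tr$first_density == "a" & tr$last_density == "a"], 1L)

  sim <- small_sim(n = 400, seed = 10)
  trs <- transition_table(sim, "ai")
  expect_equal(sum(trs$n), n_women(sim))

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_sankey_csv(trs, tmp)
  sk <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_named(sk, c("source_category", "target_category", "count"))
  expect_equal(sum(sk$count), n_women(sim))
})
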