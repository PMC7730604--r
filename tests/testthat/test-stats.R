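test_that("Fisher two-sided p matches hand-enumerable tables", {
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  # diagonal 3s: only a = 0 and a = 3 are as unlikely as observed -> 2/20
  expect_equal(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  # margins forcing a single outcome
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 2, 3), 2))$p_value, 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)), "negative")
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "positive")
})

test_that("Fisher implementation agrees with stats::fisher.test", {
  tables <- list(
    c(5, 2, 3, 9), c(10, 10, 10, 10), c(1, 9, 11, 3),
    c(0, 5, 8, 2), c(12, 0, 0, 7), c(2, 1, 0, 4),
    c(21, 23, 5932, 29037), # large-margin stability
    c(100, 250, 3000, 40000)
  )
  for (tb in tables) {
    m <- matrix(tb, 2)
    expect_equal(
      fisher_exact_two_sided(m)$p_value,
      stats::fisher.test(m)$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("Fisher p is invariant under transpose and row/column swap", {
  withr::with_seed(60, {
    for (i in 1:25) {
      m <- matrix(rpois(4, 6), 2)
      if (sum(m) == 0) next
      p <- fisher_exact_two_sided(m)$p_value
      expect_equal(fisher_exact_two_sided(t(m))$p_value, p)
      expect_equal(
        fisher_exact_two_sided(m[2:1, 2:1])$p_value, p
      )
    }
  })
})

test_that("sample odds ratio is ad/bc with infinities allowed", {
  expect_equal(
    fisher_exact_two_sided(matrix(c(4, 2, 1, 3), 2))$odds_ratio, 6
  )
  expect_equal(
    fisher_exact_two_sided(matrix(c(4, 0, 1, 3), 2))$odds_ratio, Inf
  )
})

test_that("Wilcoxon rank-sum: exact for small tie-free samples", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1) # 2 / choose(6, 3) extreme assignments
  expect_equal(w$method, "exact")
  # identical multisets are maximally unsurprising
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # degenerate single-valued input
  expect_warning(
    w2 <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)),
    "degenerate"
  )
  expect_equal(w2$p_value, 1)
  # ties or large n switch to the corrected normal approximation
  w3 <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_match(w3$method, "continuity correction")
  expect_equal(
    w3$p_value,
    suppressWarnings(
      stats::wilcox.test(c(1, 2, 2, 3), c(2, 4, 5, 6),
        exact = FALSE, correct = TRUE
      )$p.value
    )
  )
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("percent rounds half away from zero and keeps the fraction", {
  expect_equal(percent(2670, 45393)$label, "6%")
  expect_equal(percent(1359, 3915)$label, "35%")
  expect_equal(percent(25, 44)$label, "57%")
  expect_equal(percent(1, 8)$label, "13%") # 12.5 rounds up, not to even
  expect_equal(percent(3, 4)$fraction, 0.75)
  expect_error(percent(1, 0), "positive")
  # label times denominator reproduces the numerator within rounding error
  withr::with_seed(71, {
    for (i in 1:50) {
      b <- sample(1:500, 1)
      a <- sample(0:b, 1)
      pct <- as.numeric(sub("%", "", percent(a, b)$label))
      expect_lte(abs(pct * b / 100 - a), b / 200 + 1e-9)
    }
  })
})

test_that("the enrichment report delegates to the underlying tests", {
  data <- tibble::tibble(
    set = rep(c("exRTE", "n-exRTE"), c(44, 34969)),
    recent = c(
      rep(c(TRUE, FALSE), c(21, 23)),
      rep(c(TRUE, FALSE), c(5932, 29037))
    ),
    score = seq_len(44 + 34969) %% 97 + ifelse(
      rep(c(TRUE, FALSE), c(44, 34969)), 5, 0
    )
  )
  rep <- enrichment_report(
    data,
    categorical = "recent", continuous = "score"
  )
  fisher_row <- rep[rep$attribute == "recent", ]
  expect_equal(
    fisher_row$p_value,
    fisher_exact_two_sided(matrix(c(21, 23, 5932, 29037), 2))$p_value
  )
  expect_equal(fisher_row$n11, 21)
  expect_equal(fisher_row$n12, 5932)
  wil_row <- rep[rep$test == "wilcoxon", ]
  expect_equal(
    wil_row$p_value,
    wilcoxon_rank_sum(data$score[data$set == "exRTE"],
      data$score[data$set != "exRTE"]
    )$p_value
  )
})

test_that("a level absent from one set still yields a defined p", {
  data <- tibble::tibble(
    set = rep(c("exRTE", "n-exRTE"), c(10, 50)),
    clade = c(rep("Ale", 10), rep(c("Ale", "Tekay"), c(20, 30)))
  )
  rep <- enrichment_report(data, categorical = "clade")
  tekay <- rep[rep$level == "Tekay", ]
  expect_equal(tekay$n11, 0) # zero cell
  expect_gte(tekay$p_value, 0)
  expect_lte(tekay$p_value, 1)
  # attribute missing everywhere is skipped with a warning
  data$empty <- NA_character_
  expect_warning(
    rep2 <- enrichment_report(data, categorical = c("clade", "empty")),
    "skipped"
  )
  expect_false("empty" %in% rep2$attribute)
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  ft <- fisher_exact_two_sided(matrix(c(3, 1, 2, 8), 2))
  td <- tidy(ft)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "p.value", "method"))
  data <- tibble::tibble(
    set = rep(c("exRTE", "n-exRTE"), each = 20),
    flag = rep(c(TRUE, FALSE), 20)
  )
  rep <- enrichment_report(data, categorical = "flag")
  g <- glance(rep)
  expect_named(g, c("n_tests", "n_significant", "min_p"))
  expect_equal(g$n_tests, nrow(rep))
})
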