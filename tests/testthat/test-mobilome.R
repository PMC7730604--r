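test_that("coverage normalization divides by the mean reference depth", {
  expect_equal(normalize_coverage(30, c(10, 10, 10, 10, 10)), 3)
  expect_equal(normalize_coverage(0, c(10, 10)), 0)
  expect_equal(normalize_coverage(15, c(10, 20)), 1)
  expect_error(normalize_coverage(10, c(0, 0)), "impossible")
  expect_error(normalize_coverage(10, numeric(0)), "impossible")
})

test_that("ACM ratios divide by the cultivar minimum", {
  expect_equal(acm_ratios(c(2, 1, 1.8)), c(2, 1, 1.8))
  expect_equal(acm_ratios(c(4, 4, 4)), c(1, 1, 1))
  expect_equal(acm_ratios(c(3, 6, 9)), c(1, 2, 3))
  expect_error(acm_ratios(c(1)), "two cultivars")
  expect_error(acm_ratios(c(0, 2)), "absent")
})

test_that("the cutoff is the largest reference-gene ACM swing", {
  one_gene <- tibble::tibble(
    gene_id = "g1", cultivar = c("a", "b", "c"), acm = c(1, 1.3, 1.7)
  )
  expect_equal(derive_acm_cutoff(one_gene), 1.7)
  noiseless <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 3),
    cultivar = rep(c("a", "b", "c"), 2), acm = 1
  )
  expect_equal(derive_acm_cutoff(noiseless), 1)
  two <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 3),
    cultivar = rep(c("a", "b", "c"), 2),
    acm = c(1, 1.2, 1.4, 1, 1.1, 1.6)
  )
  expect_equal(derive_acm_cutoff(two), 1.6)
})

test_that("mobility grouping uses strict comparisons on both counts", {
  expect_equal(classify_mobility(c(1, 1.8, 2.1), 1.7)$group, "group1")
  expect_equal(classify_mobility(c(1, 1.8, 1.0), 1.7)$group, "group2")
  # values equal to the cutoff do not count
  r <- classify_mobility(c(1, 1.7, 1.7), 1.7)
  expect_equal(r$n_above_cutoff, 0)
  expect_equal(r$group, "group2")
  expect_error(classify_mobility(c(1, 2), 0.5), ">= 1")
})

mk_depth <- function(rte_mult, ref_depth = 10, base = 10) {
  cultivars <- sprintf("cv%d", seq_along(rte_mult))
  dplyr::bind_rows(
    tibble::tibble(
      feature_id = "te1", feature_type = "rte",
      cultivar = cultivars, mean_depth = base * rte_mult
    ),
    tidyr::expand_grid(
      feature_id = c("ref1", "ref2"), cultivar = cultivars
    ) |>
      dplyr::mutate(feature_type = "reference_gene", mean_depth = ref_depth)
  )
}

test_that("noiseless copy multipliers come back exactly as ACM ratios", {
  res <- acm_profiles(mk_depth(c(1, 1, 3)))
  expect_equal(res$profiles$acm, c(1, 1, 3))
  expect_equal(res$cutoff, 1) # noiseless reference genes
  expect_equal(res$groups$group, "group2") # one cultivar above
})

test_that("scaling every depth in one cultivar cancels in normalization", {
  d <- mk_depth(c(1, 2, 4))
  d2 <- d |>
    dplyr::mutate(mean_depth = ifelse(
      cultivar == "cv2", mean_depth * 7, mean_depth
    ))
  r1 <- acm_profiles(d)
  r2 <- acm_profiles(d2)
  expect_equal(r1$profiles$normalized_coverage, r2$profiles$normalized_coverage)
  expect_equal(r1$profiles$acm, r2$profiles$acm)
})

test_that("elements absent in a cultivar are excluded, reported separately", {
  d <- dplyr::bind_rows(
    mk_depth(c(1, 1, 2)),
    tibble::tibble(
      feature_id = "te_absent", feature_type = "rte",
      cultivar = sprintf("cv%d", 1:3), mean_depth = c(10, 0, 10)
    )
  )
  res <- acm_profiles(d)
  expect_false("te_absent" %in% res$profiles$rte_id)
  expect_equal(res$absent$rte_id, "te_absent")
  expect_equal(res$absent$n_absent_cultivars, 1L)
})

test_that("a single planted multiplier is recovered within 10% at 5% noise", {
  # multipliers (1, ..., 1, m): the elevated cultivar's ACM tracks m. A
  # single draw divides by the minimum of the baseline cultivars, which at
  # 5% noise biases one ratio upward by a few percent, so the 10% bound is
  # asserted on the mean over replicates.
  withr::with_seed(55, {
    for (m in c(2, 3, 4)) {
      mult <- c(rep(1, 5), m)
      acm_m <- vapply(1:30, function(i) {
        noisy <- mult * stats::rnorm(6, 1, 0.05)
        res <- acm_profiles(mk_depth(noisy), cutoff = 1.7)
        # only one elevated cultivar: always group 2
        expect_equal(res$groups$group, "group2")
        res$profiles$acm[which.max(mult)]
      }, numeric(1))
      expect_lt(abs(mean(acm_m) - m) / m, 0.1)
    }
  })
})

test_that("simulated mobility grouping matches the planted truth", {
  ds <- simulate_dataset(
    small_config(depth_cv = 0.05), 29L, withr::local_tempdir()
  )
  res <- acm_profiles(ds$paths$cultivar_depth, cutoff = 1.7)
  truth_groups <- ds$truth$rtes |>
    dplyr::transmute(rte_id, truth = ifelse(mobile, "group1", "group2"))
  got <- res$groups |> dplyr::inner_join(truth_groups, by = "rte_id")
  expect_equal(nrow(got), nrow(ds$truth$rtes))
  expect_equal(got$group, got$truth)
})
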