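test_that("RPKM follows reads * 1e9 / (length * library)", {
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(10, 2000, 2e6), 2.5)
  expect_error(compute_rpkm(10, 0, 1e6), "positive")
  expect_error(compute_rpkm(10, 1000, 0), "positive")
  expect_error(compute_rpkm(-1, 1000, 1e6), "non-negative")
})

test_that("RPKM is invariant to joint scaling of counts and library size", {
  for (f in c(0.5, 2, 10, 1000)) {
    expect_equal(
      compute_rpkm(17 * f, 1234, 2e6 * f),
      compute_rpkm(17, 1234, 2e6)
    )
  }
})

test_that("breadth of coverage counts positions at or above min depth", {
  expect_equal(covered_fraction(c(1, 1, 0, 0, 1)), 0.6)
  expect_equal(covered_fraction(rep(0, 10)), 0)
  expect_equal(covered_fraction(c(5, 5, 5)), 1)
  expect_equal(covered_fraction(c(1, 2, 3), min_depth = 2), 2 / 3)
  expect_error(covered_fraction(numeric(0)), "empty")
})

make_profiles <- function(rpkm, breadth, samples = c("leaf", "NaCl_3h")) {
  tidyr::expand_grid(rte_id = "r1", sample = samples) |>
    dplyr::mutate(
      condition = ifelse(sample == "leaf", "non-stressed", "stressed"),
      rpkm = rpkm, covered_fraction = breadth,
      read_count = 1L, library_size = 1e6
    )
}

test_that("the expression call needs RPKM, breadth, and a long domain hit", {
  rte <- mk_rte("r1", 0, 2000,
    domains = tibble::tibble(
      domain = "GAG", aa_length = 100L, start = 100L, end = 400L
    )
  )
  call1 <- call_expressed(make_profiles(c(10, 10), c(0.9, 0.9)), rte)
  expect_true(call1$is_expressed)
  expect_equal(call1$set, "exRTE")
  # high RPKM but low breadth everywhere -> not expressed
  expect_false(call_expressed(
    make_profiles(c(5, 5), c(0.3, 0.3)), rte
  )$is_expressed)
  # high breadth but RPKM below threshold -> not expressed
  expect_false(call_expressed(
    make_profiles(c(0.1, 0.1), c(0.8, 0.8)), rte
  )$is_expressed)
  # short domain match is curated away
  rte_short <- mk_rte("r1", 0, 2000,
    domains = tibble::tibble(
      domain = "GAG", aa_length = 49L, start = 100L, end = 247L
    )
  )
  expect_false(call_expressed(
    make_profiles(c(10, 10), c(0.9, 0.9)), rte_short
  )$is_expressed)
  # thresholds are inclusive
  expect_true(call_expressed(
    make_profiles(c(0.25, 0), c(0.6, 0)), rte
  )$is_expressed)
})

test_that("RPKM and breadth may pass in different samples unless strict", {
  rte <- mk_rte("r1", 0, 2000,
    domains = tibble::tibble(
      domain = "RT", aa_length = 100L, start = 100L, end = 400L
    )
  )
  # sample 1 passes RPKM only, sample 2 passes breadth only
  prof <- make_profiles(c(10, 0.1), c(0.3, 0.9))
  expect_true(call_expressed(prof, rte)$is_expressed)
  expect_false(
    call_expressed(prof, rte, strict_same_sample = TRUE)$is_expressed
  )
})

test_that("exRTE and n-exRTE always partition the catalog", {
  ds <- simulate_dataset(small_config(), 3L, withr::local_tempdir())
  cat <- read_ltr_gff(ds$paths$rte_gff)
  prof <- expression_profiles(
    cat, ds$paths$counts, ds$paths$libraries, ds$paths$depth
  )
  calls <- call_expressed(
    prof, cat,
    seqs = rte_sequences(cat, ds$paths$genome)
  )
  expect_setequal(calls$rte_id, cat$rte_id)
  expect_true(all(calls$set %in% c("exRTE", "n-exRTE")))
  expect_equal(
    sum(calls$set == "exRTE") + sum(calls$set == "n-exRTE"), nrow(cat)
  )
  # is_expressed implies both evidence flags
  expect_true(all(
    !calls$is_expressed | (calls$passes_rpkm & calls$passes_coverage)
  ))
})

test_that("condition partition counts detections by stress status", {
  prof <- dplyr::bind_rows(
    make_profiles(c(10, 0), c(0.9, 0)) |> dplyr::mutate(rte_id = "only_ns"),
    make_profiles(c(0, 10), c(0, 0.9)) |> dplyr::mutate(rte_id = "only_st"),
    make_profiles(c(10, 10), c(0.9, 0.9)) |> dplyr::mutate(rte_id = "both"),
    make_profiles(c(0, 0), c(0, 0)) |> dplyr::mutate(rte_id = "silent")
  )
  part <- condition_partition(prof)
  expect_equal(part$non_stressed_only, 1)
  expect_equal(part$stressed_only, 1)
  expect_equal(part$both, 1)
  # silent element is excluded entirely
  expect_equal(sum(unlist(part)), 3)
  bad <- prof |> dplyr::mutate(condition = "weird")
  expect_error(condition_partition(bad), "unknown condition")
})
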