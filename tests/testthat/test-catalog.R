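test_that("parsing the emitted annotation recovers every planted element", {
  ds <- simulate_dataset(small_config(), 21L, withr::local_tempdir())
  cat <- read_ltr_gff(ds$paths$rte_gff)
  tr <- ds$truth$rtes
  expect_equal(nrow(cat), nrow(tr))
  m <- match(tr$rte_id, cat$rte_id)
  expect_false(anyNA(m))
  expect_equal(cat$start[m], tr$start)
  expect_equal(cat$end[m], tr$end)
  expect_equal(cat$ltr5_start[m], tr$ltr5_start)
  expect_equal(cat$ltr3_end[m], tr$ltr3_end)
  expect_equal(cat$superfamily[m], tr$superfamily)
  expect_equal(cat$clade[m], tr$clade)
  # domain labels round-trip exactly
  got <- purrr::map(cat$domain_hits[m], function(h) sort(unique(h$domain)))
  want <- purrr::map(tr$orf_domains, function(d) sort(unique(d)))
  expect_equal(got, want)
})

test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  f <- write_gff_fixture(c(
    "chr1\tx\tLTR_retrotransposon\t1\t10\t.\t+\t.\tID=e1",
    "chr1\tx\tlong_terminal_repeat\t1\t3\t.\t+\t.\tParent=e1",
    "chr1\tx\tlong_terminal_repeat\t8\t10\t.\t+\t.\tParent=e1"
  ))
  cat <- read_ltr_gff(f)
  expect_equal(cat$start, 0L)
  expect_equal(cat$end, 10L)
  expect_equal(cat$ltr5_end, 3L)
  expect_equal(cat$ltr3_start, 7L)
  expect_equal(nrow(cat$domain_hits[[1]]), 0)
})

test_that("elements without exactly two LTR children are skipped, warned", {
  f <- write_gff_fixture(c(
    "chr1\tx\tLTR_retrotransposon\t1\t100\t.\t+\t.\tID=bad",
    "chr1\tx\tlong_terminal_repeat\t1\t10\t.\t+\t.\tParent=bad",
    "chr1\tx\tLTR_retrotransposon\t201\t300\t.\t+\t.\tID=good",
    "chr1\tx\tlong_terminal_repeat\t201\t210\t.\t+\t.\tParent=good",
    "chr1\tx\tlong_terminal_repeat\t291\t300\t.\t+\t.\tParent=good"
  ))
  expect_warning(cat <- read_ltr_gff(f), "bad")
  expect_equal(cat$rte_id, "good")
})

test_that("candidate filter applies strict length and domain-evidence rules", {
  rtes <- dplyr::bind_rows(
    mk_rte("len501_gag", 0, 501,
      domains = tibble::tibble(
        domain = "GAG", aa_length = 80L, start = 20L, end = 260L
      )
    ),
    mk_rte("len500_rt", 1000, 1500,
      domains = tibble::tibble(
        domain = "RT", aa_length = 80L, start = 1020L, end = 1260L
      )
    ),
    mk_rte("len2000_nodomain", 3000, 5000,
      domains = tibble::tibble(
        domain = character(), aa_length = integer(),
        start = integer(), end = integer()
      )
    )
  )
  kept <- filter_candidates(rtes)
  expect_equal(kept$rte_id, "len501_gag")
  # idempotent
  expect_equal(filter_candidates(kept), kept)
})

test_that("global identity follows the stated alignment scoring", {
  expect_equal(global_identity("ACGT", "ACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)
  expect_equal(global_identity("ACGT", "ACG"), 0.75)
  expect_equal(
    global_identity("ACGT", "ACG"),
    global_identity("ACG", "ACGT")
  )
  expect_error(global_identity("", "ACG"), "non-empty")
})

test_that("redundancy removal is greedy by length with deterministic ties", {
  a <- mutate_ltr(strrep("ACGT", 250), 0, 0) # 1000 bp
  rtes <- dplyr::bind_rows(
    mk_rte("dup_first", 0, 1000),
    mk_rte("dup_second", 5000, 6000)
  )
  seqs <- c(dup_first = a, dup_second = a)
  kept <- remove_redundant(rtes, seqs)
  expect_equal(kept$rte_id, "dup_first") # tie -> smaller coordinate
})

test_that("greedy dedup keeps the non-conflicting set along a chain", {
  set.seed(33)
  a <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  b <- mutate_ltr(a, 0.03, 0.01, seed = 1L) # ~96% identical to a
  c_ <- mutate_ltr(b, 0.03, 0.01, seed = 2L) # ~96% to b, ~92% to a
  # the premise of the chain
  expect_gt(global_identity(a, b), 0.95)
  expect_gt(global_identity(b, c_), 0.95)
  expect_lte(global_identity(a, c_), 0.95)
  rtes <- dplyr::bind_rows(
    mk_rte("A", 0, 1000), mk_rte("B", 2000, 3000), mk_rte("C", 4000, 5000)
  )
  kept <- remove_redundant(rtes, c(A = a, B = b, C = c_))
  expect_equal(kept$rte_id, c("A", "C"))
  # both members of a 90%-identity pair survive
  d <- mutate_ltr(a, 0.07, 0.03, seed = 3L)
  expect_lt(global_identity(a, d), 0.95)
  kept2 <- remove_redundant(
    dplyr::bind_rows(mk_rte("A", 0, 1000), mk_rte("D", 2000, 3000)),
    c(A = a, D = d)
  )
  expect_setequal(kept2$rte_id, c("A", "D"))
  # retained set has pairwise identity below the cutoff
  ids <- kept$rte_id
  seqs <- c(A = a, B = b, C = c_)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      expect_lte(global_identity(seqs[[ids[i]]], seqs[[ids[j]]]), 0.95)
    }
  }
})
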