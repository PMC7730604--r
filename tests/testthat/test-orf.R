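test_that("ORF length boundary is inclusive at the minimum", {
  # ATG + 99 codons + stop: 300 nt, kept
  orfs <- find_orfs(orf_nt(99))
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$nt_length, 300L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 300L) # stop codon excluded from the span
  expect_equal(nchar(orfs$protein), 100)
  expect_equal(substr(orfs$protein, 1, 1), "M")
  # ATG + 98 codons + stop: 297 nt, dropped
  expect_equal(nrow(find_orfs(orf_nt(98))), 0)
})

test_that("reverse-strand ORFs are reported in input coordinates", {
  left <- strrep("C", 50)
  right <- strrep("C", 70)
  seq <- paste0(left, revcomp_test(orf_nt(99)), right)
  orfs <- find_orfs(seq)
  minus <- orfs[orfs$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$nt_length, 300L)
  # cassette occupies [50, 50+303); the ORF (stop excluded on the minus
  # strand, i.e. the 3 leftmost bases of the cassette) is [53, 353)
  expect_equal(minus$start, 53L)
  expect_equal(minus$end, 353L)
  expect_equal(substr(minus$protein, 1, 1), "M")
})

test_that("a sequence and its reverse complement yield mirror ORF sets", {
  set.seed(8)
  base <- paste(
    sample(c("A", "C", "G", "T"), 400, replace = TRUE),
    collapse = ""
  )
  seq <- paste0(base, orf_nt(110), base)
  fwd <- find_orfs(seq)
  rev <- find_orfs(revcomp_test(seq))
  n <- nchar(seq)
  mirrored <- tibble::tibble(
    start = n - rev$end, end = n - rev$start,
    strand = ifelse(rev$strand == "+", "-", "+"),
    nt_length = rev$nt_length, protein = rev$protein
  ) |> dplyr::arrange(start, strand)
  fwd_cmp <- fwd |>
    dplyr::select(start, end, strand, nt_length, protein) |>
    dplyr::arrange(start, strand)
  expect_equal(fwd_cmp, mirrored, ignore_attr = TRUE)
})

test_that("ambiguous codons truncate an ORF at the first N", {
  # 110 clean codons, an NNN codon, then more codons and a stop
  seq <- paste0("ATG", strrep("GCT", 110), "NNN", strrep("GCT", 20), "TAA")
  orfs <- find_orfs(seq)
  plus <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$nt_length, 3L * 111L) # ATG + 110 codons
})

test_that("RBM scan counts non-overlapping CCHC motifs left to right", {
  expect_equal(scan_rbm("CAACAAAAHAAAAC"), 1L)
  expect_equal(scan_rbm("MKVLNNN"), 0L)
  expect_equal(scan_rbm(strrep("CAACAAAAHAAAAC", 2)), 2L)
  # invariant under appending non-C/H residues
  expect_equal(scan_rbm(paste0("CAACAAAAHAAAAC", strrep("QSTV", 20))), 1L)
  # vectorized
  expect_equal(scan_rbm(c("CAACAAAAHAAAAC", "AAAA")), c(1L, 0L))
})

test_that("domain labels attach via peptide tags or an external hit table", {
  orfs <- tibble::tibble(
    orf_id = c("o1", "o2"),
    protein = c(
      paste0("MAAA", domain_tags()[["GAG"]], "AAAA"),
      "MKLVNNNPQRST"
    )
  )
  tagged <- label_orfs(orfs)
  expect_equal(tagged$domain, c("GAG", "none"))
  hits <- tibble::tibble(orf_id = "o2", domain = "RT")
  by_hits <- label_orfs(orfs, hits = hits)
  expect_equal(by_hits$domain, c("none", "RT"))
})

test_that("the RBM FDR is the motif rate among non-GAG ORFs", {
  orfs <- tibble::tibble(
    domain = c(rep("GAG", 10), rep("none", 45393)),
    rbm_count = c(rep(1L, 10), rep(1L, 2670), rep(0L, 45393 - 2670)),
    protein = "M"
  )
  res <- compute_rbm_fdr(orfs)
  expect_equal(res$summary$n_nongag_orfs, 45393)
  expect_equal(res$summary$n_nongag_with_rbm, 2670)
  expect_equal(res$summary$fdr, 2670 / 45393)
  expect_equal(percent(
    res$summary$n_nongag_with_rbm, res$summary$n_nongag_orfs
  )$label, "6%")
  # no motifs anywhere -> fdr 0; no non-GAG ORFs -> undefined
  expect_equal(
    compute_rbm_fdr(tibble::tibble(
      domain = c("GAG", "none"), rbm_count = c(0L, 0L)
    ))$summary$fdr, 0
  )
  expect_true(is.na(compute_rbm_fdr(tibble::tibble(
    domain = "GAG", rbm_count = 1L
  ))$summary$fdr))
})

test_that("a planted motif-background rate is recovered by the FDR", {
  n <- 10000L
  rate <- 0.10
  rbm <- withr::with_seed(77, stats::rbinom(n, 1, rate))
  orfs <- tibble::tibble(domain = "none", rbm_count = as.integer(rbm))
  fdr <- compute_rbm_fdr(orfs)$summary$fdr
  expect_lt(abs(fdr - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("per-element domain sets, full-length flag, and combinations", {
  orfs <- tibble::tibble(
    rte_id = c("r1", "r1", "r2", "r2", "r2", "r2", "r2"),
    domain = c("GAG", "RT", "GAG", "AP", "INT", "RT", "RH"),
    nt_length = c(300L, 600L, 300L, 300L, 300L, 900L, 300L)
  )
  rtes <- tibble::tibble(
    rte_id = c("r1", "r2", "r3"),
    set = c("exRTE", "exRTE", "n-exRTE")
  )
  s <- summarize_domains(orfs, rtes)
  expect_equal(
    s$per_rte$domains[s$per_rte$rte_id == "r1"], "GAG;RT"
  )
  expect_false(s$per_rte$full_length[s$per_rte$rte_id == "r1"])
  expect_true(s$per_rte$full_length[s$per_rte$rte_id == "r2"])
  expect_equal(s$per_rte$max_orf_nt[s$per_rte$rte_id == "r2"], 900L)
  # element without ORFs gets the empty combination
  expect_equal(s$per_rte$domains[s$per_rte$rte_id == "r3"], "")
  expect_equal(s$per_rte$n_orfs[s$per_rte$rte_id == "r3"], 0L)
  expect_true(all(c("set", "domains") %in% names(s$combinations)))
})
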