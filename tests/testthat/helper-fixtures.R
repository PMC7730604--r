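# Fixtures are built in code at test time; nothing binary is stored.

# A reduced simulation: one 200-kb chromosome, 10 elements, 3 samples,
# 6 cultivars. Small enough for repeated end-to-end runs.
small_config <- function(...) {
  simulation_config(
    n_chrom = 1L, chrom_length = 200000L,
    n_rte = 10L, n_expressed = 5L,
    samples = tibble::tibble(
      sample = c("leaf", "NaCl_3h", "PEG_6h"),
      condition = c("non-stressed", "stressed", "stressed")
    ),
    n_cultivars = 6L,
    ...
  )
}

# Minimal catalog row for unit tests that do not need a genome.
mk_rte <- function(rte_id, start, end, chrom = "chr1", strand = "+",
                   ltr_len = 10L,
                   domains = tibble::tibble(
                     domain = "RT", aa_length = 100L,
                     start = start + ltr_len, end = start + ltr_len + 300L
                   )) {
  tibble::tibble(
    rte_id = rte_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    length = as.integer(end - start),
    ltr5_start = as.integer(start), ltr5_end = as.integer(start + ltr_len),
    ltr3_start = as.integer(end - ltr_len), ltr3_end = as.integer(end),
    superfamily = NA_character_, clade = NA_character_,
    domain_hits = list(domains)
  )
}

# Write GFF3 lines (1-based inclusive) to a temp file.
write_gff_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

seq_to_chars_test <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revcomp_test <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# An ORF cassette: ATG + n_codons sense codons + TAA, flanked as requested.
orf_nt <- function(n_codons, codon = "GCT") {
  paste0("ATG", strrep(codon, n_codons), "TAA")
}
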