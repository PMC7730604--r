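# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed. Components get fixed
# offsets so that, e.g., adding RNA-seq samples never perturbs the genome
# sequence stream. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, component) {
  offsets <- c(
    sequence = 101L, placement = 211L, expression = 307L,
    cultivar = 401L, orf = 503L, age = 601L, misc = 701L
  )
  off <- offsets[[component]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Run `code` under a fixed seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Transition partner of each base (A<->G, C<->T).
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# The two transversion targets of each base.
TRANSVERSION <- list(
  A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G")
)

RTE_DOMAINS <- c("GAG", "AP", "INT", "RT", "RH")

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# 0-based half-open interval [start, end) -> GRanges (1-based inclusive).
interval_to_granges <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}
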