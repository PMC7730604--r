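# Catalog of LTR retrotransposon annotations: parsing the LTRdigest-style
# GFF3 dialect, candidate filtering, and redundancy removal.

#' Parse an LTRdigest-style retrotransposon GFF3
#'
#' Reads a GFF3 file with `LTR_retrotransposon` features whose children are
#' two `long_terminal_repeat` features and any number of `protein_match`
#' features (attributes `Name` = domain symbol, `aa_length` = match length in
#' amino acids). Children are attached by `Parent` attribute, falling back to
#' containment when `Parent` is absent. GFF3 1-based inclusive coordinates
#' are converted to the package's internal 0-based half-open convention.
#' Elements without exactly two LTR children are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per element: `rte_id`, `chrom`, `start`,
#'   `end`, `strand`, `length`, `ltr5_start/end`, `ltr3_start/end`,
#'   `superfamily`, `clade`, and a list-column `domain_hits` of tibbles
#'   (`domain`, `aa_length`, `start`, `end`).
#' @export
read_ltr_gff <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(x) {
      if (length(x)) as.character(x[1]) else NA_character_
    }, character(1))
  } else {
    rep(NA_character_, length(gr))
  }

  is_elem <- type == "LTR_retrotransposon"
  if (!any(is_elem)) {
    return(empty_catalog())
  }
  elems <- gr[is_elem]
  elem_ids <- id[is_elem]
  if (anyNA(elem_ids)) abort("LTR_retrotransposon features must carry ID")

  get_attr <- function(md, name, idx) {
    if (name %in% names(md)) as.character(md[[name]])[idx] else NA_character_
  }

  rows <- vector("list", length(elems))
  kept <- logical(length(elems))
  for (i in seq_along(elems)) {
    eid <- elem_ids[i]
    child <- which(parent == eid)
    if (length(child) == 0) {
      # fall back to containment on the same chromosome
      child <- which(
        !is_elem &
          as.character(GenomicRanges::seqnames(gr)) ==
            as.character(GenomicRanges::seqnames(elems[i])) &
          GenomicRanges::start(gr) >= GenomicRanges::start(elems[i]) &
          GenomicRanges::end(gr) <= GenomicRanges::end(elems[i])
      )
    }
    ltrs <- child[type[child] == "long_terminal_repeat"]
    if (length(ltrs) != 2) {
      warn(sprintf(
        "element %s has %d LTR children (expected 2); skipped",
        eid, length(ltrs)
      ))
      next
    }
    ltrs <- ltrs[order(GenomicRanges::start(gr)[ltrs])]
    pm <- child[type[child] == "protein_match"]
    hits <- tibble(
      domain = get_attr(md, "Name", pm),
      aa_length = as.integer(get_attr(md, "aa_length", pm)),
      start = GenomicRanges::start(gr)[pm] - 1L,
      end = GenomicRanges::end(gr)[pm]
    )
    rows[[i]] <- tibble(
      rte_id = eid,
      chrom = as.character(GenomicRanges::seqnames(elems[i])),
      start = GenomicRanges::start(elems[i]) - 1L,
      end = GenomicRanges::end(elems[i]),
      strand = {
        s <- as.character(GenomicRanges::strand(elems[i]))
        if (s == "*") "+" else s
      },
      ltr5_start = GenomicRanges::start(gr)[ltrs[1]] - 1L,
      ltr5_end = GenomicRanges::end(gr)[ltrs[1]],
      ltr3_start = GenomicRanges::start(gr)[ltrs[2]] - 1L,
      ltr3_end = GenomicRanges::end(gr)[ltrs[2]],
      superfamily = get_attr(md, "superfamily", which(is_elem)[i]),
      clade = get_attr(md, "clade", which(is_elem)[i]),
      domain_hits = list(hits)
    )
    kept[i] <- TRUE
  }
  out <- bind_rows(rows[kept])
  out |> mutate(length = .data$end - .data$start, .after = "strand")
}

empty_catalog <- function() {
  tibble(
    rte_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    length = integer(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    superfamily = character(), clade = character(),
    domain_hits = list()
  )
}

#' Keep candidate retrotransposons by length and domain evidence
#'
#' Retains elements strictly longer than `min_len` that have at least one
#' protein-match hit to a canonical retroelement domain (GAG, AP, INT, RT,
#' RH). Input order is preserved; the operation is idempotent.
#'
#' @param rtes Catalog tibble from [read_ltr_gff()].
#' @param min_len Minimum element length, exclusive (bp).
#' @param required_domains Domain symbols that count as evidence.
#' @return The filtered catalog tibble.
#' @export
filter_candidates <- function(rtes, min_len = 500,
                              required_domains = RTE_DOMAINS) {
  has_domain <- purrr::map_lgl(
    rtes$domain_hits,
    function(h) any(h$domain %in% required_domains)
  )
  rtes |> filter(.data$length > min_len, has_domain)
}

nw_alignment <- function(a, b) {
  Biostrings::pairwiseAlignment(
    a, b,
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE
    ),
    gapOpening = 0, gapExtension = 2
  )
}

#' Global alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, linear gap -2);
#' identity is the number of matching columns divided by the total alignment
#' columns (gap columns included in the denominator). Symmetric in its
#' arguments.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' global_identity("ACGT", "ACGT") # 1
#' global_identity("ACGT", "ACGA") # 0.75
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  pa <- nw_alignment(a, b)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / ncol_aln
}

#' Remove redundant (highly similar) elements
#'
#' Greedy clustering: elements are processed by descending length (ties by
#' chromosome then smaller start coordinate); an element is discarded when
#' its [global_identity()] with any already-retained element's sequence
#' exceeds `identity_cutoff`. The retained set therefore has pairwise
#' identity `<= identity_cutoff`. A cheap length-ratio bound
#' (identity can never exceed shorter/longer length) prunes hopeless
#' alignments.
#'
#' @param rtes Catalog tibble.
#' @param seqs Named character vector (or `DNAStringSet`) of element
#'   sequences keyed by `rte_id`.
#' @param identity_cutoff Identity above which an element is redundant.
#' @return The retained subset of `rtes`, in original row order.
#' @export
remove_redundant <- function(rtes, seqs, identity_cutoff = 0.95) {
  if (nrow(rtes) <= 1) {
    return(rtes)
  }
  if (!is.character(seqs)) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  missing <- setdiff(rtes$rte_id, names(seqs))
  if (length(missing)) {
    abort(sprintf("no sequence for element(s): %s", paste(missing, collapse = ", ")))
  }
  ord <- order(-rtes$length, rtes$chrom, rtes$start)
  retained_idx <- integer(0)
  for (i in ord) {
    s_i <- seqs[[rtes$rte_id[i]]]
    redundant <- FALSE
    for (j in retained_idx) {
      s_j <- seqs[[rtes$rte_id[j]]]
      n_short <- min(nchar(s_i), nchar(s_j))
      n_long <- max(nchar(s_i), nchar(s_j))
      if (n_short / n_long <= identity_cutoff) next
      if (global_identity(s_i, s_j) > identity_cutoff) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained_idx <- c(retained_idx, i)
  }
  rtes[sort(retained_idx), ]
}

#' Extract element (or LTR) sequences from a genome
#'
#' @param rtes Catalog tibble.
#' @param genome A `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet()`) or path to a FASTA file.
#' @param what `"element"`, `"ltr5"`, or `"ltr3"`.
#' @return Named character vector of sequences keyed by `rte_id`;
#'   minus-strand elements are reverse-complemented.
#' @export
rte_sequences <- function(rtes, genome, what = c("element", "ltr5", "ltr3")) {
  what <- match.arg(what)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  cols <- switch(what,
    element = c("start", "end"),
    ltr5 = c("ltr5_start", "ltr5_end"),
    ltr3 = c("ltr3_start", "ltr3_end")
  )
  out <- vapply(seq_len(nrow(rtes)), function(i) {
    s <- as.character(Biostrings::subseq(
      genome[[rtes$chrom[i]]],
      start = rtes[[cols[1]]][i] + 1L,
      end = rtes[[cols[2]]][i]
    ))
    if (rtes$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, rtes$rte_id)
}

#' Write the catalog as a TSV table
#'
#' @param rtes Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(rtes, path) {
  flat <- rtes |>
    mutate(
      domains = purrr::map_chr(
        .data$domain_hits,
        function(h) paste(sort(unique(h$domain)), collapse = ";")
      )
    ) |>
    select(-"domain_hits")
  readr::write_tsv(flat, path)
  invisible(path)
}
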