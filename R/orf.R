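# ORF prediction, domain labeling, and the CCHC zinc-knuckle (RNA-binding
# motif) screen with its empirical false-discovery rate.

STOP_CODONS <- c("TAA", "TAG", "TGA")

orf_scan_one_strand <- function(seq, min_nt, strand, total_len) {
  n <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3
    if (n_codons < 1) next
    starts <- f + seq(1L, by = 3L, length.out = n_codons)
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_ambig <- grepl("[^ACGT]", codons)
    is_start <- codons == "ATG"
    cur <- NA_integer_
    for (i in seq_len(n_codons)) {
      if (is_stop[i] || is_ambig[i]) {
        # a stop terminates an ORF; an ambiguous codon truncates it there
        if (!is.na(cur)) {
          len <- 3L * (i - cur)
          if (len >= min_nt) {
            s0 <- f + 3L * (cur - 1L) # 0-based within this strand's sequence
            e0 <- s0 + len
            rows[[length(rows) + 1]] <- tibble(
              start = if (strand == "+") s0 else total_len - e0,
              end = if (strand == "+") e0 else total_len - s0,
              strand = strand,
              frame = if (strand == "+") f + 1L else -(f + 1L),
              nt_length = len,
              protein = as.character(Biostrings::translate(
                Biostrings::DNAString(substr(seq, s0 + 1L, e0)),
                no.init.codon = TRUE
              ))
            )
          }
          cur <- NA_integer_
        }
      } else if (is.na(cur) && is_start[i]) {
        cur <- i
      }
    }
  }
  bind_rows(rows)
}

#' Find open reading frames in all six frames
#'
#' Reports every maximal start-codon-to-stop region (the span runs from the
#' first ATG after the previous terminator through the last codon before the
#' stop; the stop codon is excluded) of at least `min_nt` nucleotides.
#' Reverse-strand ORFs are reported in the coordinates of the input sequence
#' with strand `-`. ORFs containing an ambiguous (N) codon are truncated at
#' that codon. Trailing frames without a stop codon are not reported.
#'
#' @param seq Nucleotide string over A, C, G, T, N.
#' @param min_nt Minimum ORF length in nucleotides (start codon included,
#'   stop excluded; always a multiple of 3).
#' @return Tibble: `start`, `end` (0-based half-open), `strand`, `frame`
#'   (1..3 forward, -1..-3 reverse), `nt_length`, `protein`.
#' @export
find_orfs <- function(seq, min_nt = 300) {
  if (!is.character(seq) || length(seq) != 1) {
    abort("`seq` must be a single nucleotide string")
  }
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd <- orf_scan_one_strand(seq, min_nt, "+", n)
  rev <- orf_scan_one_strand(revcomp(seq), min_nt, "-", n)
  out <- bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(tibble(
      start = integer(), end = integer(), strand = character(),
      frame = integer(), nt_length = integer(), protein = character()
    ))
  }
  out |> arrange(.data$start, .data$strand, .data$frame)
}

#' Find ORFs for every element of a catalog
#'
#' @param rtes Catalog tibble.
#' @param genome `DNAStringSet` or FASTA path.
#' @param min_nt Minimum ORF length (nt).
#' @return Tibble of ORFs with `rte_id` and `orf_id` columns; coordinates
#'   are within the element.
#' @export
find_orfs_catalog <- function(rtes, genome, min_nt = 300) {
  seqs <- rte_sequences(rtes, genome, "element")
  out <- purrr::map2(rtes$rte_id, seqs, function(id, s) {
    orfs <- find_orfs(s, min_nt)
    if (nrow(orfs)) orfs$rte_id <- id
    orfs
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(tibble(
      rte_id = character(), orf_id = character(),
      start = integer(), end = integer(), strand = character(),
      frame = integer(), nt_length = integer(), protein = character()
    ))
  }
  out |>
    mutate(orf_id = sprintf("%s_orf%02d", .data$rte_id, row_number()),
      .by = "rte_id"
    ) |>
    select("rte_id", "orf_id", dplyr::everything())
}

#' Count CCHC RNA-binding motifs in a protein
#'
#' Counts non-overlapping, left-to-right matches of the 14-residue
#' zinc-knuckle pattern `C-X2-C-X4-H-X4-C` (X = any residue).
#'
#' @param protein Amino-acid string(s); vectorized.
#' @return Integer count per input.
#' @examples
#' scan_rbm("CAACAAAAHAAAAC") # 1
#' @export
scan_rbm <- function(protein) {
  vapply(protein, function(p) {
    m <- gregexpr("C.{2}C.{4}H.{4}C", p)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Label ORFs with retroelement domains
#'
#' Two modes. With a hit table (`hits`; columns `orf_id`, `domain`, e.g.
#' parsed from a BLAST-vs-REXdb search) labels are joined by ORF id. Without
#' one, labels are recovered by exact peptide-tag match ([domain_tags()]),
#' the synthetic mode. Unlabeled ORFs get domain `"none"`. An `rbm_count`
#' column is added from [scan_rbm()] if absent.
#'
#' @param orfs ORF tibble (needs `protein`; `orf_id` for hit-table mode).
#' @param hits Optional tibble `orf_id` -> `domain`.
#' @param tags Named peptide tags for synthetic mode.
#' @return `orfs` with `domain` and `rbm_count` columns.
#' @export
label_orfs <- function(orfs, hits = NULL, tags = domain_tags()) {
  if (!is.null(hits)) {
    orfs <- orfs |>
      left_join(hits |> select("orf_id", "domain"), by = "orf_id") |>
      mutate(domain = dplyr::coalesce(.data$domain, "none"))
  } else {
    orfs$domain <- vapply(orfs$protein, function(p) {
      hit <- names(tags)[vapply(
        tags, function(t) grepl(t, p, fixed = TRUE), logical(1)
      )]
      if (length(hit)) hit[1] else "none"
    }, character(1), USE.NAMES = FALSE)
  }
  if (!"rbm_count" %in% names(orfs)) {
    orfs$rbm_count <- scan_rbm(orfs$protein)
  }
  orfs
}

#' RNA-binding-motif false-discovery rate
#'
#' The empirical FDR of the CCHC motif scan: the fraction of non-GAG ORFs
#' that nonetheless carry at least one motif. When the ORF table carries a
#' `set` column (`"exRTE"` / `"n-exRTE"`), per-set GAG/RBM counts are also
#' reported at both granularities (ORFs and elements).
#'
#' @param orfs Labeled ORF tibble (columns `domain`, `rbm_count`; optionally
#'   `set` and `rte_id`).
#' @return A list: `summary` (one-row tibble with `n_gag_orfs`,
#'   `n_gag_with_rbm`, `n_nongag_orfs`, `n_nongag_with_rbm`, `fdr`) and
#'   `by_set` (per-set counts, `NULL` without a `set` column). `fdr` is `NA`
#'   when there are no non-GAG ORFs.
#' @export
compute_rbm_fdr <- function(orfs) {
  gag <- orfs$domain == "GAG"
  has_rbm <- orfs$rbm_count > 0
  n_nongag <- sum(!gag)
  summary <- tibble(
    n_gag_orfs = sum(gag),
    n_gag_with_rbm = sum(gag & has_rbm),
    n_nongag_orfs = n_nongag,
    n_nongag_with_rbm = sum(!gag & has_rbm),
    fdr = if (n_nongag == 0) NA_real_ else sum(!gag & has_rbm) / n_nongag
  )
  by_set <- NULL
  if ("set" %in% names(orfs)) {
    by_set <- orfs |>
      group_by(.data$set) |>
      summarise(
        n_gag_orfs = sum(.data$domain == "GAG"),
        n_gag_orfs_with_rbm = sum(.data$domain == "GAG" & .data$rbm_count > 0),
        n_elements_with_gag = dplyr::n_distinct(
          .data$rte_id[.data$domain == "GAG"]
        ),
        n_elements_with_rbm_gag = dplyr::n_distinct(
          .data$rte_id[.data$domain == "GAG" & .data$rbm_count > 0]
        ),
        .groups = "drop"
      )
  }
  list(summary = summary, by_set = by_set)
}

#' Per-element domain sets and combination table
#'
#' Summarizes, per element, the set of domains encoded across its ORFs, a
#' full-length flag (all of GAG, AP, INT, RT, RH present), the longest ORF,
#' and the ORF count; plus an aggregate domain-combination frequency table
#' (per set when the catalog carries one).
#'
#' @param orfs Labeled ORF tibble (columns `rte_id`, `domain`, `nt_length`).
#' @param rtes Catalog tibble (optionally with a `set` column); elements
#'   without ORFs get an empty combination.
#' @return A list: `per_rte` tibble (`rte_id`, `domains`, `full_length`,
#'   `max_orf_nt`, `n_orfs`, and `set` if available) and `combinations`
#'   frequency tibble.
#' @export
summarize_domains <- function(orfs, rtes) {
  per_orf <- orfs |>
    filter(.data$domain != "none") |>
    group_by(.data$rte_id) |>
    summarise(
      domains = paste(
        RTE_DOMAINS[RTE_DOMAINS %in% unique(.data$domain)],
        collapse = ";"
      ),
      full_length = all(RTE_DOMAINS %in% .data$domain),
      .groups = "drop"
    )
  lens <- if (nrow(orfs) == 0) {
    tibble(rte_id = character(), max_orf_nt = integer(), n_orfs = integer())
  } else {
    orfs |>
      group_by(.data$rte_id) |>
      summarise(
        max_orf_nt = max(.data$nt_length), n_orfs = dplyr::n(),
        .groups = "drop"
      )
  }
  per_rte <- rtes |>
    select(dplyr::any_of(c("rte_id", "set"))) |>
    left_join(per_orf, by = "rte_id") |>
    left_join(lens, by = "rte_id") |>
    mutate(
      domains = dplyr::coalesce(.data$domains, ""),
      full_length = dplyr::coalesce(.data$full_length, FALSE),
      max_orf_nt = dplyr::coalesce(.data$max_orf_nt, 0L),
      n_orfs = dplyr::coalesce(.data$n_orfs, 0L)
    )
  grouping <- intersect(c("set", "domains"), names(per_rte))
  combinations <- per_rte |>
    count(across(all_of(grouping)), name = "n_elements")
  list(per_rte = per_rte, combinations = combinations)
}
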