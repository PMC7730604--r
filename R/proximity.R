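# Distance from each element to its nearest annotated gene, with the four
# proximity categories: insertion (element inside a gene), overlapped,
# close (< 1 kb), distant (>= 1 kb).

#' Read a gene annotation GFF3
#'
#' Keeps `gene` features (full gene spans, introns/UTRs included) and
#' converts coordinates to 0-based half-open.
#'
#' @param path GFF3 path.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  md <- S4Vectors::mcols(gr)
  tibble(
    gene_id = if ("ID" %in% names(md)) {
      as.character(md$ID)
    } else {
      sprintf("gene_%05d", seq_along(gr))
    },
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Nearest gene and proximity category for each element
#'
#' For every element, finds the nearest gene on the same chromosome (strand
#' ignored) and classifies the pair: `insertion` when the element lies
#' entirely inside the gene, `overlapped` when the intervals share at least
#' one base without containment, `close` when the gap is below `close_bp`
#' (adjacent intervals have gap 0 and are close), `distant` otherwise
#' (a gap of exactly `close_bp` is distant). Elements on a chromosome
#' without genes get an infinite distance, category `distant`, and a missing
#' `gene_id`. Categories are mutually exclusive and exhaustive with
#' precedence insertion > overlapped > close/distant.
#'
#' @param rtes Catalog tibble.
#' @param genes Gene tibble from [read_gene_gff()] (0-based half-open).
#' @param close_bp Close/distant boundary in bp (default 1000).
#' @return Tibble: `rte_id`, `gene_id`, `distance`, `category`.
#' @export
classify_gene_proximity <- function(rtes, genes, close_bp = 1000) {
  if (nrow(rtes) == 0) {
    return(tibble(
      rte_id = character(), gene_id = character(),
      distance = numeric(), category = character()
    ))
  }
  out <- tibble(
    rte_id = rtes$rte_id,
    gene_id = NA_character_,
    distance = Inf,
    category = "distant"
  )
  if (nrow(genes) > 0) {
    rte_gr <- interval_to_granges(rtes$chrom, rtes$start, rtes$end)
    gene_gr <- interval_to_granges(genes$chrom, genes$start, genes$end)
    near <- GenomicRanges::distanceToNearest(rte_gr, gene_gr)
    qh <- S4Vectors::queryHits(near)
    sh <- S4Vectors::subjectHits(near)
    out$gene_id[qh] <- genes$gene_id[sh]
    out$distance[qh] <- S4Vectors::mcols(near)$distance
    overlaps <- IRanges::overlapsAny(rte_gr, gene_gr)
    contained <- IRanges::overlapsAny(rte_gr, gene_gr, type = "within")
    out$category <- dplyr::case_when(
      contained ~ "insertion",
      overlaps ~ "overlapped",
      out$distance < close_bp ~ "close",
      TRUE ~ "distant"
    )
    # report the containing/overlapping gene itself, not merely the nearest
    if (any(overlaps)) {
      hits <- GenomicRanges::findOverlaps(rte_gr, gene_gr)
      first_hit <- tapply(
        S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits), min
      )
      idx <- as.integer(names(first_hit))
      out$gene_id[idx] <- genes$gene_id[first_hit]
      out$distance[idx] <- 0
    }
  }
  out
}

#' Proximity category histogram per element set
#'
#' @param proximity Tibble from [classify_gene_proximity()].
#' @param rtes Catalog tibble with a `set` column (from [call_expressed()]).
#' @return A list: `histogram` (set x category counts and fractions) and
#'   `distances` (per-element distances with set labels, for rank-sum
#'   comparisons).
#' @export
proximity_summary <- function(proximity, rtes) {
  joined <- proximity |>
    left_join(rtes |> select("rte_id", "set"), by = "rte_id")
  histogram <- joined |>
    count(.data$set, .data$category, name = "n") |>
    group_by(.data$set) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  list(
    histogram = histogram,
    distances = joined |> select("rte_id", "set", "distance")
  )
}
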