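# Expression evidence per element: RPKM, breadth of coverage, and the
# expressed / not-expressed call.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = read_count * 1e9 / (length * library_size)`. Vectorized; scaling
#' `read_count` and `library_size` by the same factor leaves the value
#' unchanged.
#'
#' @param read_count Mapped reads assigned to the feature (>= 0).
#' @param length Feature length in bp (> 0).
#' @param library_size Total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(10, 1000, 1e6) # 10
#' @export
compute_rpkm <- function(read_count, length, library_size) {
  if (any(length <= 0)) abort("`length` must be positive")
  if (any(library_size <= 0)) abort("`library_size` must be positive")
  if (any(read_count < 0)) abort("`read_count` must be non-negative")
  read_count * 1e9 / (length * library_size)
}

#' Breadth of coverage from a per-base depth vector
#'
#' Fraction of positions covered at or above `min_depth`.
#'
#' @param depth Numeric vector of per-base depths over the interval.
#' @param min_depth Minimum depth for a base to count as covered.
#' @return Fraction in `[0, 1]`.
#' @export
covered_fraction <- function(depth, min_depth = 1) {
  if (length(depth) == 0) abort("empty interval")
  mean(depth >= min_depth)
}

# Breadth of coverage of each element from bedGraph intervals
# (0-based half-open), without materializing per-base vectors.
breadth_from_bedgraph <- function(bedgraph, rtes, min_depth = 1) {
  if (is.character(bedgraph)) {
    if (file.size(bedgraph) == 0) {
      return(setNames(rep(0, nrow(rtes)), rtes$rte_id))
    }
    bedgraph <- rtracklayer::import(bedgraph, format = "bedGraph")
  }
  bedgraph <- bedgraph[S4Vectors::mcols(bedgraph)$score >= min_depth]
  rte_gr <- interval_to_granges(rtes$chrom, rtes$start, rtes$end)
  cov_bp <- rep(0L, nrow(rtes))
  if (length(bedgraph)) {
    hits <- GenomicRanges::findOverlaps(rte_gr, bedgraph)
    if (length(hits)) {
      inter_w <- GenomicRanges::width(IRanges::pintersect(
        rte_gr[S4Vectors::queryHits(hits)],
        bedgraph[S4Vectors::subjectHits(hits)]
      ))
      agg <- tapply(inter_w, S4Vectors::queryHits(hits), sum)
      cov_bp[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  setNames(cov_bp / (rtes$end - rtes$start), rtes$rte_id)
}

#' Build per-sample expression profiles for a catalog
#'
#' Combines a read-count table, per-sample library sizes, and per-sample
#' depth bedGraphs into one long profile table with RPKM and breadth of
#' coverage per element and sample. Elements missing from the count table
#' are treated as zero evidence (with a message).
#'
#' @param rtes Catalog tibble.
#' @param counts Tibble with columns `rte_id`, `sample`, `read_count`, or a
#'   TSV path.
#' @param libraries Tibble with columns `sample`, `condition`,
#'   `library_size`, or a TSV path.
#' @param depth_paths Named character vector of bedGraph paths keyed by
#'   sample name (0-based half-open intervals, 4th column = depth).
#' @param min_depth Depth at which a base counts as covered.
#' @return Long tibble: `rte_id`, `sample`, `condition`, `read_count`,
#'   `library_size`, `rpkm`, `covered_fraction`.
#' @export
expression_profiles <- function(rtes, counts, libraries, depth_paths,
                                min_depth = 1) {
  if (is.character(counts)) counts <- readr::read_tsv(counts, show_col_types = FALSE)
  if (is.character(libraries)) {
    libraries <- readr::read_tsv(libraries, show_col_types = FALSE)
  }
  grid <- tidyr::expand_grid(
    rte_id = rtes$rte_id, sample = libraries$sample
  )
  prof <- grid |>
    left_join(counts, by = c("rte_id", "sample")) |>
    left_join(
      libraries |> select("sample", "condition", "library_size"),
      by = "sample"
    )
  n_missing <- length(setdiff(rtes$rte_id, unique(counts$rte_id)))
  if (n_missing > 0) {
    inform(sprintf(
      "%d element(s) absent from the count table; treated as zero evidence",
      n_missing
    ))
  }
  # an empty count table may be read with unguessable column types
  prof$read_count <- as.numeric(prof$read_count)
  prof$read_count[is.na(prof$read_count)] <- 0
  lens <- setNames(rtes$end - rtes$start, rtes$rte_id)
  prof <- prof |>
    mutate(rpkm = compute_rpkm(
      .data$read_count, lens[.data$rte_id], .data$library_size
    ))
  breadth <- purrr::imap(depth_paths, function(f, s) {
    tibble(
      rte_id = rtes$rte_id, sample = s,
      covered_fraction = unname(breadth_from_bedgraph(f, rtes, min_depth))
    )
  }) |> bind_rows()
  prof |>
    left_join(breadth, by = c("rte_id", "sample")) |>
    mutate(covered_fraction = dplyr::coalesce(.data$covered_fraction, 0))
}

#' Call expressed elements (exRTEs)
#'
#' An element is called expressed when (1) RPKM passes `rpkm_min` in at
#' least one sample, (2) breadth of coverage passes `cov_min` in at least
#' one sample, and (3) its best protein-domain match is at least
#' `min_domain_aa` amino acids. By default the RPKM and coverage criteria
#' may be met in different samples; `strict_same_sample = TRUE` requires one
#' sample satisfying both. With `pooled_coverage = TRUE` breadth is
#' evaluated on the per-base maximum across samples (approximated here by
#' the per-sample maximum breadth; the default per-sample mode is the
#' primary interface). When sequences are supplied, redundancy removal
#' ([remove_redundant()]) is applied to the expressed set; elements dropped
#' there fall back into the non-expressed set, so
#' `exRTE` and `n-exRTE` always partition the catalog.
#'
#' @param profiles Long profile tibble from [expression_profiles()].
#' @param rtes Catalog tibble.
#' @param rpkm_min Minimum RPKM (inclusive).
#' @param cov_min Minimum breadth of coverage (inclusive).
#' @param min_domain_aa Minimum best domain-hit length (amino acids).
#' @param seqs Optional named element sequences for redundancy removal.
#' @param dedup_identity Identity cutoff for redundancy removal.
#' @param strict_same_sample Require RPKM and coverage in the same sample.
#' @param pooled_coverage Evaluate coverage pooled across samples.
#' @return The catalog tibble with logical columns `passes_rpkm`,
#'   `passes_coverage`, `passes_domain`, `redundant`, `is_expressed`, and
#'   `set` (`"exRTE"` / `"n-exRTE"`).
#' @export
call_expressed <- function(profiles, rtes, rpkm_min = 0.25, cov_min = 0.60,
                           min_domain_aa = 50, seqs = NULL,
                           dedup_identity = 0.95,
                           strict_same_sample = FALSE,
                           pooled_coverage = FALSE) {
  per_rte <- profiles |>
    group_by(.data$rte_id) |>
    summarise(
      passes_rpkm = any(.data$rpkm >= rpkm_min),
      passes_coverage = if (pooled_coverage) {
        max(.data$covered_fraction) >= cov_min
      } else {
        any(.data$covered_fraction >= cov_min)
      },
      passes_both_same = any(
        .data$rpkm >= rpkm_min & .data$covered_fraction >= cov_min
      ),
      .groups = "drop"
    )
  out <- rtes |>
    left_join(per_rte, by = "rte_id") |>
    mutate(
      passes_rpkm = dplyr::coalesce(.data$passes_rpkm, FALSE),
      passes_coverage = dplyr::coalesce(.data$passes_coverage, FALSE),
      passes_both_same = dplyr::coalesce(.data$passes_both_same, FALSE),
      passes_domain = purrr::map_lgl(
        .data$domain_hits,
        function(h) nrow(h) > 0 && max(h$aa_length) >= min_domain_aa
      ),
      is_expressed = if (strict_same_sample) {
        .data$passes_both_same & .data$passes_domain
      } else {
        .data$passes_rpkm & .data$passes_coverage & .data$passes_domain
      }
    ) |>
    select(-"passes_both_same")
  out$redundant <- FALSE
  if (!is.null(seqs) && any(out$is_expressed)) {
    expressed <- out |> filter(.data$is_expressed)
    keep <- remove_redundant(expressed, seqs, dedup_identity)
    out$redundant <- out$is_expressed & !(out$rte_id %in% keep$rte_id)
    out$is_expressed <- out$is_expressed & !out$redundant
  }
  out |> mutate(set = if_else(.data$is_expressed, "exRTE", "n-exRTE"))
}

#' Partition detected elements by stress condition
#'
#' An element counts as detected in a sample when both RPKM and breadth pass
#' their thresholds in that sample. Returns how many elements are detected
#' only in non-stressed samples, only in stressed samples, and in both
#' (elements never detected are excluded).
#'
#' @param profiles Long profile tibble (must carry a `condition` column with
#'   values `"non-stressed"` / `"stressed"`).
#' @param rpkm_min,cov_min Per-sample detection thresholds.
#' @return One-row tibble: `non_stressed_only`, `stressed_only`, `both`.
#' @export
condition_partition <- function(profiles, rpkm_min = 0.25, cov_min = 0.60) {
  if (anyNA(profiles$condition)) abort("every sample must carry a condition")
  bad <- setdiff(unique(profiles$condition), c("non-stressed", "stressed"))
  if (length(bad)) {
    abort(sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  det <- profiles |>
    mutate(detected = .data$rpkm >= rpkm_min &
      .data$covered_fraction >= cov_min) |>
    group_by(.data$rte_id) |>
    summarise(
      ns = any(.data$detected & .data$condition == "non-stressed"),
      st = any(.data$detected & .data$condition == "stressed"),
      .groups = "drop"
    )
  tibble(
    non_stressed_only = sum(det$ns & !det$st),
    stressed_only = sum(det$st & !det$ns),
    both = sum(det$ns & det$st)
  )
}
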