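# Copy-number variation across cultivars: normalized coverage, ACM ratios
# (coverage relative to the cultivar minimum), a cutoff derived from
# single-copy reference genes, and mobility groups.

#' Normalize element depth by reference single-copy genes
#'
#' Divides an element's mean depth by the unweighted mean of the reference
#' genes' mean depths in the same cultivar; the result is a dimensionless
#' copy-number proxy (1 for a single-copy locus, in expectation).
#'
#' @param rte_depth Mean per-base depth over the element (one cultivar).
#' @param ref_depths Mean depths of the reference genes in that cultivar.
#' @return Normalized coverage.
#' @examples
#' normalize_coverage(30, c(10, 10, 10, 10, 10)) # 3
#' @export
normalize_coverage <- function(rte_depth, ref_depths) {
  if (length(ref_depths) == 0 || all(ref_depths == 0)) {
    abort("normalization impossible: no reference gene with positive depth")
  }
  rte_depth / mean(ref_depths)
}

#' ACM ratios for one element across cultivars
#'
#' Each cultivar's normalized coverage divided by the minimum normalized
#' coverage of the element across all cultivars, so the minimum ratio is 1
#' and values above the reference-derived cutoff indicate additional copies.
#'
#' @param values Normalized coverage per cultivar (>= 2 values, minimum > 0).
#' @return ACM ratio vector (same order; min = 1).
#' @examples
#' acm_ratios(c(3, 6, 9)) # 1 2 3
#' @export
acm_ratios <- function(values) {
  if (length(values) < 2) abort("need at least two cultivars")
  m <- min(values)
  if (m <= 0) {
    abort(paste(
      "ACM undefined: zero minimum coverage",
      "(element absent in some cultivar; report as presence/absence variation)"
    ))
  }
  values / m
}

#' ACM cutoff from single-copy reference genes
#'
#' For each reference gene, the maximum ACM value across cultivars is
#' divided by its minimum ACM value (1 by construction); the cutoff is the
#' maximum of these over all reference genes -- the largest apparent
#' copy-number swing a true single-copy locus shows, so only elements
#' exceeding it are called as having additional copies.
#'
#' @param ref_acm Tibble with columns `gene_id` and `acm` (ACM ratios of the
#'   reference genes across cultivars).
#' @return The cutoff (a scalar >= 1).
#' @export
derive_acm_cutoff <- function(ref_acm) {
  per_gene <- ref_acm |>
    group_by(.data$gene_id) |>
    summarise(swing = max(.data$acm) / min(.data$acm), .groups = "drop")
  max(per_gene$swing)
}

#' Mobility group from ACM ratios
#'
#' Counts cultivars whose ACM ratio strictly exceeds the cutoff; elements
#' with additional copies in more than one cultivar form group 1, the rest
#' group 2.
#'
#' @param acm ACM ratio vector for one element.
#' @param cutoff ACM cutoff (>= 1).
#' @return A list: `n_above_cutoff`, `group` (`"group1"` / `"group2"`).
#' @examples
#' classify_mobility(c(1, 1.8, 2.1), 1.7)$group # "group1"
#' @export
classify_mobility <- function(acm, cutoff) {
  if (cutoff < 1) abort("`cutoff` must be >= 1")
  n_above <- sum(acm > cutoff)
  list(
    n_above_cutoff = n_above,
    group = if (n_above > 1) "group1" else "group2"
  )
}

#' ACM profiles, cutoff, and mobility groups for a depth table
#'
#' Full mobilome analysis: normalizes every element's per-cultivar depth by
#' the mean reference-gene depth of that cultivar (so per-cultivar
#' library-size differences cancel), forms ACM ratios, derives the cutoff
#' from the reference genes (or uses a fixed override, e.g. 1.7), and
#' assigns mobility groups. Elements with zero depth in any cultivar are
#' excluded from ACM and reported as presence/absence variation.
#'
#' @param depth Tibble with columns `feature_id`, `feature_type`
#'   (`"rte"` / `"reference_gene"`), `cultivar`, `mean_depth`; or a TSV path.
#' @param cutoff `"derived"` (default) or a fixed numeric cutoff.
#' @return An `exrte_acm` object: list with `profiles` (long tibble:
#'   `rte_id`, `cultivar`, `mean_depth`, `normalized_coverage`, `acm`),
#'   `groups` (`rte_id`, `n_above_cutoff`, `group`), `cutoff`,
#'   `cutoff_source`, `ref_acm`, and `absent` (presence/absence table).
#' @export
acm_profiles <- function(depth, cutoff = "derived") {
  if (is.character(depth) && length(depth) == 1 && file.exists(depth)) {
    depth <- readr::read_tsv(depth, show_col_types = FALSE)
  }
  need <- c("feature_id", "feature_type", "cultivar", "mean_depth")
  if (!all(need %in% names(depth))) {
    abort(sprintf("`depth` needs columns: %s", paste(need, collapse = ", ")))
  }
  ref <- depth |> filter(.data$feature_type == "reference_gene")
  if (nrow(ref) == 0) abort("no reference genes in the depth table")
  ref_means <- ref |>
    group_by(.data$cultivar) |>
    summarise(ref_mean = mean(.data$mean_depth), .groups = "drop")
  if (any(ref_means$ref_mean <= 0)) {
    abort("normalization impossible: a cultivar has zero reference depth")
  }

  rte <- depth |>
    filter(.data$feature_type == "rte") |>
    left_join(ref_means, by = "cultivar") |>
    mutate(normalized_coverage = .data$mean_depth / .data$ref_mean)

  absent <- rte |>
    group_by(feature_id = .data$feature_id) |>
    summarise(
      n_absent_cultivars = sum(.data$mean_depth == 0),
      .groups = "drop"
    ) |>
    filter(.data$n_absent_cultivars > 0) |>
    rename(rte_id = "feature_id")

  usable <- rte |> filter(!(.data$feature_id %in% absent$rte_id))
  profiles <- if (nrow(usable) == 0) {
    tibble(
      rte_id = character(), cultivar = character(),
      mean_depth = numeric(), normalized_coverage = numeric(),
      acm = numeric()
    )
  } else {
    usable |>
      group_by(.data$feature_id) |>
      mutate(acm = acm_ratios(.data$normalized_coverage)) |>
      ungroup() |>
      select(
        rte_id = "feature_id", "cultivar", "mean_depth",
        "normalized_coverage", "acm"
      )
  }

  ref_acm <- ref |>
    left_join(ref_means, by = "cultivar") |>
    mutate(normalized_coverage = .data$mean_depth / .data$ref_mean) |>
    group_by(gene_id = .data$feature_id) |>
    mutate(acm = acm_ratios(.data$normalized_coverage)) |>
    ungroup() |>
    select("gene_id", "cultivar", "acm")

  if (identical(cutoff, "derived")) {
    cut_val <- derive_acm_cutoff(ref_acm)
    cut_src <- "derived"
  } else {
    cut_val <- as.numeric(cutoff)
    cut_src <- "fixed"
  }

  groups <- profiles |>
    group_by(.data$rte_id) |>
    summarise(
      n_above_cutoff = sum(.data$acm > cut_val),
      .groups = "drop"
    ) |>
    mutate(group = if_else(.data$n_above_cutoff > 1, "group1", "group2"))

  structure(
    list(
      profiles = profiles, groups = groups,
      cutoff = cut_val, cutoff_source = cut_src,
      ref_acm = ref_acm, absent = absent
    ),
    class = "exrte_acm"
  )
}

#' @export
print.exrte_acm <- function(x, ...) {
  cat(sprintf(
    "ACM mobilome analysis: %d elements x %d cultivars; cutoff %.3f (%s)\n",
    dplyr::n_distinct(x$profiles$rte_id),
    dplyr::n_distinct(x$profiles$cultivar),
    x$cutoff, x$cutoff_source
  ))
  print(count(x$groups, .data$group))
  if (nrow(x$absent)) {
    cat(sprintf(
      "%d element(s) excluded (zero depth in some cultivar)\n", nrow(x$absent)
    ))
  }
  invisible(x)
}
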