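# Broom-style tidiers for the package's result objects.

#' Tidy a Fisher test result
#'
#' @param x An `exrte_fisher` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (sample odds ratio), `p.value`,
#'   `method`.
#' @export
tidy.exrte_fisher <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio, p.value = x$p_value,
    method = "Fisher's Exact Test for Count Data (two-sided)"
  )
}

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x An `exrte_wilcoxon` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `method`.
#' @export
tidy.exrte_wilcoxon <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}

#' Tidy an enrichment report
#'
#' @param x An `exrte_enrichment` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.exrte_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "exrte_enrichment")
  out
}

#' Summarize an enrichment report
#'
#' @param x An `exrte_enrichment` tibble.
#' @param alpha Significance threshold for the significant-test count.
#' @param ... Unused.
#' @return One-row tibble: `n_tests`, `n_significant`, `min_p`.
#' @export
glance.exrte_enrichment <- function(x, alpha = 0.05, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_value < alpha),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' Tidy an ACM mobilome result
#'
#' @param x An `exrte_acm` object.
#' @param ... Unused.
#' @return Long tibble of per-element, per-cultivar ACM ratios with group
#'   labels.
#' @export
tidy.exrte_acm <- function(x, ...) {
  x$profiles |> left_join(x$groups, by = "rte_id")
}

#' Summarize an ACM mobilome result
#'
#' @param x An `exrte_acm` object.
#' @param ... Unused.
#' @return One-row tibble: `n_elements`, `n_cultivars`, `cutoff`,
#'   `n_group1`, `n_group2`, `n_absent`.
#' @export
glance.exrte_acm <- function(x, ...) {
  tibble(
    n_elements = dplyr::n_distinct(x$profiles$rte_id),
    n_cultivars = dplyr::n_distinct(x$profiles$cultivar),
    cutoff = x$cutoff,
    n_group1 = sum(x$groups$group == "group1"),
    n_group2 = sum(x$groups$group == "group2"),
    n_absent = nrow(x$absent)
  )
}
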