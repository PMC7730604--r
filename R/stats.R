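# Set-comparison statistics: two-sided Fisher's exact test (minimum-
# likelihood convention, log-factorial arithmetic), Wilcoxon rank-sum, and
# rounded-percent reporting.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the probability
#' of the observed table (the minimum-likelihood convention, as printed by
#' R's `fisher.test`). Probabilities are compared with a relative tolerance
#' of 1e-7 to guard against floating-point ties, and computed via
#' log-binomial coefficients, numerically stable for table totals in the
#' tens of thousands. The reported odds ratio is the sample odds ratio
#' `ad/bc` (`Inf` allowed).
#'
#' @param table 2x2 matrix of non-negative integer counts (or a length-4
#'   vector, filled column-wise).
#' @return An `exrte_fisher` object: `table`, `p_value`, `odds_ratio`.
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2))$p_value # 0.1
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ])
  c1 <- sum(table[, 1])
  n <- sum(table)
  if (n == 0) abort("at least one margin must be positive")

  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(n - r1, c1 - support) - lchoose(n, c1)
  lp_obs <- lp[support == a]
  # minimum-likelihood convention with relative tolerance on probabilities
  p <- sum(exp(lp[lp <= lp_obs + log1p(1e-7)]))
  p <- min(1, p)

  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(
    list(table = table, p_value = p, odds_ratio = or),
    class = "exrte_fisher"
  )
}

#' @export
print.exrte_fisher <- function(x, ...) {
  cat("Fisher's Exact Test for Count Data (two-sided)\n")
  print(x$table)
  cat(sprintf("p-value = %.4g, sample odds ratio = %.4g\n", x$p_value, x$odds_ratio))
  invisible(x)
}

#' Wilcoxon rank-sum test between two samples
#'
#' Two-sided rank-sum comparison via [stats::wilcox.test()]: exact when both
#' samples have at most 25 observations and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction. The
#' mode actually used is recorded in the result (and reported via
#' `message()` when `verbose = TRUE`). Degenerate input in which every value
#' is identical yields p = 1 with a warning.
#'
#' @param x,y Non-empty numeric samples.
#' @param verbose Announce the mode used.
#' @return An `exrte_wilcoxon` object: `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, verbose = FALSE) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warn("degenerate input: all values identical; p = 1")
    return(structure(
      list(statistic = NA_real_, p_value = 1, method = "degenerate"),
      class = "exrte_wilcoxon"
    ))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 25 && length(y) <= 25 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  method <- if (use_exact) {
    "exact"
  } else {
    "normal approximation with continuity correction"
  }
  if (verbose) inform(sprintf("wilcoxon_rank_sum: %s mode", method))
  structure(
    list(
      statistic = unname(wt$statistic), p_value = wt$p.value, method = method
    ),
    class = "exrte_wilcoxon"
  )
}

#' @export
print.exrte_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank sum test (%s): W = %s, p-value = %.4g\n",
    x$method, format(x$statistic), x$p_value
  ))
  invisible(x)
}

#' Rounded percent with label
#'
#' `100 * numerator / denominator`, rounded half away from zero to the
#' nearest integer and formatted as `"<n>%"`; the raw fraction is returned
#' alongside.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @return A list: `label` (e.g. `"57%"`), `fraction`, `numerator`,
#'   `denominator`.
#' @examples
#' percent(25, 44)$label # "57%"
#' @export
percent <- function(numerator, denominator) {
  if (denominator <= 0) abort("`denominator` must be positive")
  fraction <- numerator / denominator
  pct <- 100 * fraction
  rounded <- sign(pct) * floor(abs(pct) + 0.5)
  list(
    label = sprintf("%d%%", as.integer(rounded)),
    fraction = fraction,
    numerator = numerator,
    denominator = denominator
  )
}

#' Enrichment report: exRTE vs n-exRTE attribute comparisons
#'
#' For every categorical attribute, builds the 2x2 table (attribute level
#' present/absent x exRTE/n-exRTE) and runs the two-sided Fisher test --
#' multi-level attributes are tested one level against the rest, zero cells
#' allowed; for every continuous attribute, compares the two sets with the
#' Wilcoxon rank-sum test. Raw p-values are reported without
#' multiple-testing correction. Attributes missing for all elements are
#' skipped with a warning.
#'
#' @param data Per-element tibble with a `set` column (`"exRTE"` /
#'   `"n-exRTE"`) plus attribute columns.
#' @param categorical,continuous Character vectors of column names.
#' @return An `exrte_enrichment` tibble: `attribute`, `level`, `test`,
#'   counts (`n11`..`n22` for Fisher; `n_ex`, `n_nex` for Wilcoxon),
#'   `odds_ratio`, `statistic`, `p_value`.
#' @export
enrichment_report <- function(data, categorical = character(),
                              continuous = character()) {
  if (!"set" %in% names(data)) abort("`data` needs a `set` column")
  is_ex <- data$set == "exRTE"
  rows <- list()
  for (col in categorical) {
    v <- data[[col]]
    if (all(is.na(v))) {
      warn(sprintf("attribute `%s` missing for all elements; skipped", col))
      next
    }
    lv <- if (is.logical(v)) TRUE else sort(unique(v[!is.na(v)]))
    for (level in lv) {
      has <- !is.na(v) & v == level
      tab <- matrix(
        c(
          sum(has & is_ex), sum(!has & is_ex),
          sum(has & !is_ex), sum(!has & !is_ex)
        ),
        nrow = 2,
        dimnames = list(c("present", "absent"), c("exRTE", "n-exRTE"))
      )
      ft <- fisher_exact_two_sided(tab)
      rows[[length(rows) + 1]] <- tibble(
        attribute = col, level = as.character(level), test = "fisher",
        n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1], n22 = tab[2, 2],
        n_ex = NA_integer_, n_nex = NA_integer_,
        odds_ratio = ft$odds_ratio, statistic = NA_real_,
        p_value = ft$p_value
      )
    }
  }
  for (col in continuous) {
    v <- data[[col]]
    x <- v[is_ex & !is.na(v)]
    y <- v[!is_ex & !is.na(v)]
    if (length(x) == 0 || length(y) == 0) {
      warn(sprintf("attribute `%s` missing for a whole set; skipped", col))
      next
    }
    wt <- wilcoxon_rank_sum(x, y)
    rows[[length(rows) + 1]] <- tibble(
      attribute = col, level = NA_character_, test = "wilcoxon",
      n11 = NA_integer_, n12 = NA_integer_,
      n21 = NA_integer_, n22 = NA_integer_,
      n_ex = length(x), n_nex = length(y),
      odds_ratio = NA_real_, statistic = wt$statistic, p_value = wt$p_value
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("exrte_enrichment", class(out))
  out
}
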