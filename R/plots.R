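# ggplot2 visualizations for the result objects.

#' Heatmap of log2 ACM ratios
#'
#' Elements by cultivars, tile-filled with log2 of the ACM ratio; elements
#' are ordered by mobility group.
#'
#' @param object An `exrte_acm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exrte_acm <- function(object, ...) {
  df <- tidy(object)
  lev <- object$groups |>
    arrange(.data$group, .data$rte_id) |>
    pull(.data$rte_id)
  df$rte_id <- factor(df$rte_id, levels = lev)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$cultivar, y = .data$rte_id, fill = log2(.data$acm))
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 ACM") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
      space = "free_y"
    ) +
    ggplot2::labs(
      x = "cultivar", y = NULL,
      title = sprintf("ACM ratios (cutoff %.2f)", object$cutoff)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Bar chart of enrichment p-values
#'
#' One bar per comparison, height -log10(p), with the 0.05 line marked.
#'
#' @param object An `exrte_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exrte_enrichment <- function(object, ...) {
  df <- tidy(object) |>
    mutate(label = if_else(
      is.na(.data$level), .data$attribute,
      paste0(.data$attribute, ": ", .data$level)
    ))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$label, -.data$p_value),
      y = -log10(.data$p_value), fill = .data$test
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 p", title = "exRTE vs n-exRTE") +
    ggplot2::theme_minimal()
}

#' Insertion-time distributions by element set
#'
#' Density of insertion times (Mya) for expressed and non-expressed
#' elements, with the recency boundary marked.
#'
#' @param ages Age tibble from [estimate_ages()].
#' @param rtes Catalog tibble with a `set` column.
#' @param boundary_mya Recency boundary (Mya) to mark.
#' @return A ggplot.
#' @export
plot_age_distribution <- function(ages, rtes, boundary_mya = 0.5) {
  df <- ages |>
    filter(.data$datable) |>
    left_join(rtes |> select("rte_id", "set"), by = "rte_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mya, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = boundary_mya, linetype = "dashed") +
    ggplot2::labs(
      x = "insertion time (Mya)", y = "density",
      title = "LTR-divergence insertion times"
    ) +
    ggplot2::theme_minimal()
}
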