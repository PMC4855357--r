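# ggplot2 views of the main result types.

#' @rdname sort_pool
#' @param object A `sorted_pool`.
#' @exportS3Method ggplot2::autoplot
autoplot.sorted_pool <- function(object, ...) {
  cs <- combo_summary(object) |>
    tidyr::pivot_longer(c("n_unique", "n_total"),
                        names_to = "measure", values_to = "n")
  ggplot2::ggplot(cs, ggplot2::aes(
    x = .data$combo, y = .data$n,
    colour = ifelse(.data$used, "used", "unused"), shape = .data$measure
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "tag combination", y = "sequences (log scale)", colour = NULL,
      shape = NULL,
      title = sprintf("Pool %s: unique and total sequences per tag combination",
                      object$pool)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Heat-map style view of a tag occurrence matrix
#'
#' @param x A [tag_matrix()] result.
#' @param log Use a log1p fill scale (default TRUE).
#' @return A ggplot object; forward tags on rows, reverse tags on columns.
#' @export
plot_tag_matrix <- function(x, log = TRUE) {
  df <- tidy(x) |>
    mutate(
      fwd_tag = factor(.data$fwd_tag, levels = rev(rownames(x))),
      rev_tag = factor(.data$rev_tag, levels = colnames(x)),
      fill = if (log) log1p(.data$total) else .data$total
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rev_tag, y = .data$fwd_tag,
                                   fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log) "log1p(copies)" else "copies") +
    ggplot2::labs(x = "reverse tag", y = "forward tag",
                  title = sprintf("Tag combination occupancy (pool %s)",
                                  attr(x, "pool") %||% "")) +
    ggplot2::theme_minimal()
}

#' @rdname sample_rsi
#' @param object An `rsi_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rsi_report <- function(object, ...) {
  col <- if (isTRUE(attr(object, "explicit"))) "rsi" else "mean_rsi"
  thr <- attr(object, "dissimilar_threshold") %||% 0.6
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed", colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Renkonen similarity index (0 = identical replicates)",
                  y = "count",
                  title = "Replicate comparability") +
    ggplot2::theme_minimal()
}

#' Reproducibility-by-frequency view of a sample's unique sequences
#'
#' @param tables An unfiltered `sample_tables`.
#' @param sample Sample label to plot (default: the first).
#' @param max_total Upper bound on the total copy number shown (default 10,
#'   the low-copy region where the filtering decision lives).
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(tables, sample = NULL, max_total = 10) {
  rt <- reproducibility_table(tables)
  sample <- sample %||% rt$sample[1]
  df <- rt |>
    filter(.data$sample == !!sample, .data$total <= max_total) |>
    mutate(repro = sprintf("%d/%d", .data$reproducibility, .data$n_replicates))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$total), y = .data$n_unique,
                                   fill = .data$repro)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "total copy number", y = "unique sequences",
                  fill = "reproducibility",
                  title = sprintf("Sample %s: copy number vs reproducibility", sample)) +
    ggplot2::theme_minimal()
}
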