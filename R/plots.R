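#' Plot a map of alterations across chromosome extremities
#'
#' One tile per clone and extremity, coloured by the kinds of calls made
#' there (Y' structure change, terminal duplication, circularization),
#' mirroring the per-extremity alteration maps used to summarise survivor
#' clones.
#'
#' @param events Event tibble with `clone`, `extremity`, `kind` columns.
#' @param extremities Optional character vector fixing the extremity order.
#' @return A ggplot object.
#' @export
plot_alteration_map <- function(events, extremities = NULL) {
  ev <- tibble::as_tibble(events)
  ev$category <- dplyr::case_when(
    ev$kind %in% c("loss", "gain", "tandem_amplification", "new_variant") ~
      "Y' structure",
    ev$kind == "terminal_duplication" ~ "terminal duplication",
    ev$kind == "circularization" ~ "circularization",
    TRUE ~ "other")
  df <- dplyr::distinct(ev, .data$clone, .data$extremity, .data$category)
  if (!is.null(extremities)) {
    df$extremity <- factor(df$extremity, levels = extremities)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$extremity, y = .data$clone,
                                   fill = .data$category)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "chromosome extremity", y = "clone", fill = "alteration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot a Y' similarity matrix
#'
#' @param mat Similarity matrix from [similarity_matrix()].
#' @param order_by_tree Reorder rows/columns by average-linkage clustering.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(mat, order_by_tree = TRUE) {
  ord <- seq_len(nrow(mat))
  if (order_by_tree && nrow(mat) > 2) {
    ord <- stats::hclust(stats::as.dist(100 - mat), method = "average")$order
  }
  m <- mat[ord, ord]
  df <- tidyr::expand_grid(row = factor(rownames(m), levels = rownames(m)),
                           col = factor(colnames(m), levels = colnames(m)))
  df$sim <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$sim)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(mat), 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot tandem repeat arrays (unit length versus copy number)
#'
#' @param arrays Array tibble from [tcircle_analysis()] (`$arrays`).
#' @return A ggplot object.
#' @export
plot_tandem_arrays <- function(arrays) {
  df <- tibble::as_tibble(arrays)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit_len, y = .data$copies,
                                   colour = .data$clone)) +
    ggplot2::geom_jitter(width = 0, height = 0.08, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "repeat unit length (bp)", y = "copies in tandem",
                  colour = "clone") +
    ggplot2::theme_minimal()
}

#' Plot circle matches across telomeres
#'
#' Horizontal segments are the telomere tracts of one genome; coloured
#' boxes mark where each circle unit matches, so rolling-circle amplified
#' arrays appear as runs of adjacent boxes.
#'
#' @param matches Match tibble from [tcircle_analysis()] (`$matches`),
#'   filtered to one genome.
#' @param tracts Tract tibble (extremity, seq) for the same genome.
#' @return A ggplot object.
#' @export
plot_circle_matches <- function(matches, tracts) {
  tr <- tibble::tibble(extremity = tracts$extremity,
                       len = nchar(tracts$seq))
  m <- tibble::as_tibble(matches)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = tr,
                          ggplot2::aes(x = 0, xend = .data$len,
                                       y = .data$extremity,
                                       yend = .data$extremity),
                          linewidth = 0.4, colour = "black") +
    ggplot2::geom_rect(data = m,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.numeric(factor(.data$extremity,
                                                             levels = tr$extremity)) - 0.3,
                                    ymax = as.numeric(factor(.data$extremity,
                                                             levels = tr$extremity)) + 0.3,
                                    fill = .data$circle_id),
                       alpha = 0.8) +
    ggplot2::labs(x = "position in telomere (bp)", y = NULL,
                  fill = "circle") +
    ggplot2::theme_minimal()
}

#' Box plot of telomere length distributions per extremity
#'
#' Boxes span Q1-Q3 with the median marked; whiskers extend to
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR.
#'
#' @param object A `telo_lengths` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.telo_lengths <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$extremity, y = .data$length)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.6,
                          fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "chromosome extremity", y = "telomere length (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
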