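#' @title Plot helpers
#' @name plots
#' @description ggplot2 views of the main result types: stacked relative
#'   abundances, volcano-style differential-abundance panels, and PCoA
#'   ordinations of a distance matrix.
NULL

#' Stacked relative-abundance bars per sample
#'
#' @param table A taxon count table (from [build_genus_table()]).
#' @param top_n Collapse all but the `top_n` most abundant taxa into
#'   "other".
#' @return A ggplot.
#' @export
plot_relative_abundance <- function(table, top_n = 10L) {
  cm <- count_matrix(table)
  rel <- sweep(cm$counts, 2L, colSums(cm$counts), "/")
  lab <- if ("name" %in% names(table) && !all(is.na(table$name)))
    table$name else rownames(rel)
  ord <- order(rowMeans(rel), decreasing = TRUE)
  keep <- head(ord, top_n)
  lab2 <- rep("other", nrow(rel))
  lab2[keep] <- lab[keep]
  long <- as_tibble(rel) %>%
    dplyr::mutate(taxon = lab2) %>%
    tidyr::pivot_longer(-"taxon", names_to = "sample_id",
                        values_to = "rel_abundance") %>%
    dplyr::group_by(.data$taxon, .data$sample_id) %>%
    dplyr::summarise(rel_abundance = sum(.data$rel_abundance),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$rel_abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-abundance results
#'
#' @param diff Result tibble with `log2_fold_change`, `p_value` and
#'   optionally `fdr`/`significant`.
#' @param alpha Significance threshold used for coloring.
#' @return A ggplot.
#' @export
plot_volcano <- function(diff, alpha = 0.05) {
  diff <- as_tibble(diff)
  diff$sig <- if ("significant" %in% names(diff)) diff$significant
    else diff$p_value < alpha
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$log2_fold_change,
                                     y = -log10(.data$p_value),
                                     color = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "log2 fold change (treatment vs control)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' PCoA ordination of a distance matrix
#'
#' @param dist A `dist` over samples.
#' @param groups Group labels per sample.
#' @return A ggplot of the first two principal coordinates.
#' @export
plot_pcoa <- function(dist, groups) {
  d <- as.matrix(dist)
  co <- cmdscale(d, k = 2)
  df <- tibble(sample_id = rownames(d) %||% paste0("s", seq_len(nrow(d))),
               PCo1 = co[, 1], PCo2 = co[, 2],
               group = as.character(groups))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::theme_minimal()
}
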