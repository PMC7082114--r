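#' Volcano plot of a gene-level contrast
#'
#' Mean log2 fold change against `-log10` p-value, with optional gene
#' highlighting (e.g. planted sensitizers or a target set).
#'
#' @param contrast Tibble with columns `gene`, `logfc` (or `delta`) and
#'   `p_value`.
#' @param highlight Optional character vector of gene ids drawn in colour.
#' @param p_col Column holding the plotted p-value (default `"p_value"`).
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrast, highlight = NULL, p_col = "p_value") {
  lfc_col <- if ("logfc" %in% names(contrast)) "logfc" else "delta"
  df <- tibble::tibble(gene = contrast$gene,
                       logfc = contrast[[lfc_col]],
                       mlp = -log10(pmax(contrast[[p_col]], 1e-300)))
  df$hit <- df$gene %in% (highlight %||% character())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logfc, y = .data$mlp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hit), size = 0.8,
                        alpha = 0.6, show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "highlighted") +
    ggplot2::labs(x = "mean log2 fold change",
                  y = expression(-log[10] ~ "p-value")) +
    ggplot2::theme_minimal()
}

#' Plot metagene profiles
#'
#' Mean signal with a standard-error ribbon as a function of distance from
#' the TSS. Several profiles (e.g. expression bins, or target versus
#' matched control genes) can be overlaid by binding rows with a `set`
#' column.
#'
#' @param profile A [metagene_average()] tibble, optionally with a `set`
#'   column distinguishing gene sets.
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  has_set <- "set" %in% names(profile)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                             y = .data$mean))
  if (has_set) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se,
                                        fill = .data$set), alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(colour = .data$set))
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           alpha = 0.2) +
      ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "distance from TSS (bp)",
                    y = "spike-normalized signal") +
    ggplot2::theme_minimal()
}

#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) plot_metagene(object)

#' Plot PCA sample scores
#'
#' @param scores A [pca_scores()] tibble.
#' @param meta Optional sample metadata joined by `sample`; its `colour`
#'   argument column is mapped to point colour.
#' @param colour Name of a metadata column to colour by (e.g. `"group"`).
#' @return A ggplot object.
#' @export
plot_pca <- function(scores, meta = NULL, colour = NULL) {
  df <- scores
  if (!is.null(meta)) df <- dplyr::left_join(df, meta, by = "sample")
  ve <- attr(scores, "var_explained")
  lab <- function(i) {
    if (is.null(ve)) paste0("PC", i)
    else sprintf("PC%d (%.1f%%)", i, 100 * ve[i])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
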