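#' Plot a Pr_enrich sweep
#'
#' Line plot of the fraction of enriched clusters against the requested
#' cluster count K, with the selected K highlighted.
#'
#' @param object an `enrichment_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_sweep <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$K, y = .data$pr_enrich)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = tab[tab$K == object$selected_K, ],
                        colour = "red3", size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of clusters K",
                  y = "Pr_enrich (fraction of enriched clusters)",
                  title = sprintf("%s clustering: selected K = %d",
                                  object$method %||% "?",
                                  object$selected_K)) +
    ggplot2::theme_minimal()
}

#' Plot candidate modules
#'
#' Tile plot of every miRNA-cluster by mRNA-cluster candidate, shaded by
#' the association count, with regulatory modules outlined.
#'
#' @param object a `mirmod_modules`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mirmod_modules <- function(object, ...) {
  mods <- object$modules
  ggplot2::ggplot(mods, ggplot2::aes(x = .data$mrna_cluster,
                                     y = .data$mirna_cluster)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$assoc_count),
                       colour = "white") +
    ggplot2::geom_tile(data = mods[mods$regulatory, , drop = FALSE],
                       fill = NA, colour = "red3", linewidth = 0.8) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue4") +
    ggplot2::labs(x = "mRNA cluster", y = "miRNA cluster",
                  fill = "Assoc(m, n)",
                  title = "candidate miRmR modules (regulatory outlined)") +
    ggplot2::theme_minimal()
}

#' Plot a proximity matrix
#'
#' Heat map of the forest proximity, rows and columns in input order.
#'
#' @param object a `proximity_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.proximity_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(a = factor(rownames(m), levels = rownames(m)),
                           b = factor(colnames(m), levels = colnames(m)))
  df$proximity <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$proximity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "proximity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
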