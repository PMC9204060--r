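# ggplot2 views of the main result types: a volcano plot for DE tables, a
# module-trait heatmap for co-expression fits, an enrichment dot plot, and
# a simple bipartite layout for ceRNA networks.

#' Volcano plot of a DE table
#'
#' @param object A `cerna_de` tibble from [call_de()].
#' @param ... Unused.
#' @return A ggplot object (one facet per contrast).
#' @export
autoplot.cerna_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            ns = "grey60")) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Module-trait heatmap for a co-expression fit
#'
#' @param object A `coexpr_fit`.
#' @param samples Sample metadata tibble (for the trait indicators).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpr_fit <- function(object, samples, ...) {
  tr <- module_trait(object, samples)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot plot of an enrichment table
#'
#' @param enrichment Tibble from [enrich_terms()].
#' @param top Number of terms to show (by p; default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 20) {
  df <- enrichment %>%
    arrange(.data$p) %>%
    head(top) %>%
    mutate(term = factor(.data$term, levels = rev(.data$term)),
           rich_factor = .data$k / pmax(.data$K, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rich_factor, y = .data$term,
                                   size = .data$k, colour = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac") +
    ggplot2::labs(x = "rich factor (k / K)", y = NULL, size = "hits",
                  colour = "q") +
    ggplot2::theme_minimal()
}

#' Bipartite-style plot of a ceRNA triplet network
#'
#' lncRNA and mRNA nodes flank the shared miRNAs; edges are
#' lncRNA-miRNA ("sponges") and miRNA-mRNA ("targets").
#'
#' @param triplets A `cerna_triplets` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_triplets <- function(triplets, ...) {
  nodes <- triplets_to_nodes(triplets)
  edges <- triplets_to_edges(triplets)
  xpos <- c(lncRNA = 0, miRNA = 1, mRNA = 2)
  nodes <- nodes %>%
    group_by(.data$type) %>%
    mutate(y = seq_len(n()) / (n() + 1), x = xpos[.data$type[1]]) %>%
    ungroup()
  lay <- setNames(split(nodes[, c("x", "y")], seq_len(nrow(nodes))), nodes$id)
  ed <- edges %>%
    left_join(rename(nodes, from = "id", x0 = "x", y0 = "y")[, c("from", "x0", "y0")],
              by = "from") %>%
    left_join(rename(nodes, to = "id", x1 = "x", y1 = "y")[, c("to", "x1", "y1")],
              by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$type), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_x_continuous(breaks = unname(xpos),
                                labels = names(xpos), limits = c(-0.3, 2.3)) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
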