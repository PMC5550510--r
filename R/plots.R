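#' Plot the distribution of direction-specific votes
#'
#' Bar chart of how many genes received each vote count, split by
#' direction; the consensus cutoff is drawn as a dashed line.
#'
#' @param votes A vote table from [tally_votes()].
#' @param min_votes Consensus cutoff to mark.
#' @return A ggplot object.
#' @export
plot_votes <- function(votes, min_votes = 4) {
  long <- tidyr::pivot_longer(as_tibble(votes), c("up_votes", "down_votes"),
                              names_to = "direction", values_to = "votes") %>%
    mutate(direction = sub("_votes", "", .data$direction)) %>%
    filter(.data$votes > 0) %>%
    count(.data$direction, .data$votes)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$votes), y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = min_votes - 0.5, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2980b9")) +
    ggplot2::labs(x = "votes (contrasts dysregulated)", y = "genes",
                  title = "Direction-specific vote counts") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.votesig_votes <- function(object, min_votes = 4, ...) {
  plot_votes(object, min_votes = min_votes)
}

#' Dot plot of term or motif enrichment results
#'
#' Terms ordered by adjusted p-value; point size shows overlap size where
#' available.
#'
#' @param enrichment An enrichment tibble from [enrich_genes()] or
#'   [motif_enrichment()].
#' @param top_n Number of rows to display.
#' @param alpha Significance line to draw.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 15, alpha = 0.05) {
  df <- head(as_tibble(enrichment), top_n)
  lab <- if ("term_id" %in% names(df)) df$term_id else df$motif_id
  size <- if ("k" %in% names(df)) df$k else df$target_with_hit
  df <- mutate(df, label = factor(lab, levels = rev(lab)), overlap = size)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj), y = .data$label,
                                   size = .data$overlap)) +
    ggplot2::geom_point(colour = "#c0392b") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  title = "Enrichment") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.votesig_enrichment <- function(object, top_n = 15, alpha = 0.05, ...) {
  plot_enrichment(object, top_n = top_n, alpha = alpha)
}

#' @exportS3Method ggplot2::autoplot
autoplot.votesig_motif_enrichment <- function(object, top_n = 15,
                                              alpha = 0.05, ...) {
  plot_enrichment(object, top_n = top_n, alpha = alpha)
}

#' Heat map of per-contrast log2 fold changes
#'
#' Tile plot of the signature genes by contrast on the log2 scale, genes
#' ordered as given (typically by votes).
#'
#' @param fc_wide Wide tibble from [log2fc_matrix()].
#' @return A ggplot object.
#' @export
plot_log2fc_heatmap <- function(fc_wide) {
  long <- tidyr::pivot_longer(fc_wide, -"gene", names_to = "contrast",
                              values_to = "log2fc") %>%
    mutate(gene = factor(.data$gene, levels = rev(fc_wide$gene)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contrast, y = .data$gene,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", midpoint = 0,
                                  name = "log2FC") +
    ggplot2::labs(x = NULL, y = NULL, title = "Signature log2 fold changes") +
    ggplot2::theme_minimal()
}
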