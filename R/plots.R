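#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_hline geom_vline labs theme_bw scale_color_manual geom_tile
NULL

#' Forest plot of motif enrichment odds ratios
#'
#' Top motifs by lower CI bound, odds ratio with 95% CI on a log scale.
#'
#' @param object An `ml_motif_enrichment` tibble.
#' @param top_n Motifs shown (default 15).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot ml_motif_enrichment
autoplot.ml_motif_enrichment <- function(object, top_n = 15, ...) {
  df <- head(as_tibble(object), top_n)
  df$motif <- factor(df$motif, levels = rev(df$motif))
  ggplot(df, aes(x = .data$odds_ratio, y = .data$motif,
                 color = .data$enriched)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "odds ratio (95% CI)", y = NULL,
         title = "Motif enrichment among paired probes") +
    theme_bw()
}

#' Master-regulator ranking plot
#'
#' TF rank versus -log10 association p-value, highlighting the top fraction
#' and TFs in the same family as the motif's annotated TF(s).
#'
#' @param object An `ml_tf_ranking` tibble (one motif; after
#'   [classify_mrs()] family flags are shown).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot ml_tf_ranking
autoplot.ml_tf_ranking <- function(object, ...) {
  df <- as_tibble(object)
  df$highlight <- dplyr::case_when(
    "same_family" %in% names(df) & df$same_family ~ "same family",
    df$is_top_fraction ~ "top fraction",
    TRUE ~ "other"
  )
  p <- ggplot(df, aes(x = .data$rank, y = -log10(.data$pvalue),
                      color = .data$highlight)) +
    geom_point() +
    scale_color_manual(values = c("same family" = "#d95f02",
                                  "top fraction" = "#1b9e77",
                                  "other" = "grey60")) +
    labs(x = "TF rank", y = "-log10 p", color = NULL,
         title = if ("motif" %in% names(df)) {
           sprintf("TF ranking for motif %s", df$motif[1])
         } else "TF ranking") +
    theme_bw()
  p
}

#' Volcano plot of differential methylation
#'
#' @param object An `ml_dmc` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot ml_dmc
autoplot.ml_dmc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$diff, y = -log10(.data$padj),
                 color = .data$significant)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_color_manual(values = c("TRUE" = "#e41a1c", "FALSE" = "grey60")) +
    labs(x = "beta difference (group 1 - group 2)", y = "-log10 padj",
         color = "DMC") +
    theme_bw()
}

#' Methylation/expression scatter plot for one probe-gene pair
#'
#' @param dataset A [paired_omics] object.
#' @param probe_id,gene_id Pair to plot.
#' @return A ggplot object colored by group when labels exist.
#' @export
plot_pair <- function(dataset, probe_id, gene_id) {
  df <- pair_scatter_data(dataset, probe_id, gene_id)
  p <- ggplot(df, aes(x = .data$meth, y = .data$expr))
  p <- if (all(is.na(df$group))) p + geom_point()
       else p + geom_point(aes(color = .data$group))
  p + labs(x = sprintf("%s methylation (beta)", probe_id),
           y = sprintf("%s expression (log2)", gene_id)) +
    theme_bw()
}

#' Binary master-regulator membership heat map across analyses
#'
#' @param object An `ml_mr_clusters` tibble from [cross_analysis_cluster()].
#' @param mr_matrix The binary matrix that was clustered (TF rownames).
#' @param ... Ignored.
#' @return A ggplot object with TFs ordered by the clustering tree.
#' @exportS3Method ggplot2::autoplot ml_mr_clusters
autoplot.ml_mr_clusters <- function(object, mr_matrix, ...) {
  tree <- attr(object, "tree")
  ord <- tree$labels[tree$order]
  if (is.data.frame(mr_matrix)) {
    rn <- as.character(mr_matrix[[1]])
    mr_matrix <- as.matrix(mr_matrix[, -1, drop = FALSE])
    rownames(mr_matrix) <- rn
  }
  df <- as_tibble(as.data.frame(as.table(mr_matrix * 1)))
  names(df) <- c("tf", "analysis", "member")
  df$tf <- factor(df$tf, levels = ord)
  df <- left_join(df, as_tibble(object), by = "tf")
  ggplot(df, aes(x = .data$analysis, y = .data$tf,
                 fill = factor(.data$member))) +
    geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c("0" = "grey92", "1" = "#08519c"),
                               name = "MR") +
    labs(x = NULL, y = NULL) +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
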