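#' Plot the fitted guide enrichment mixture
#'
#' Histogram of guide log2 fold-changes with the fitted empirical null
#' (scaled by the estimated null mass) and alternative component overlaid.
#'
#' @param object A [fit_guide_mixture()] fit.
#' @param bins Histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.guide_mixture_fit <- function(object, bins = 60, ...) {
  df <- object$guide_data
  p_alt <- object$p_functional * object$pi_guide
  grid <- tibble(
    log2fc = seq(min(df$log2fc), max(df$log2fc), length.out = 400)
  ) |>
    mutate(
      null = (1 - p_alt) * dnorm(.data$log2fc, object$null$mu, object$null$sd),
      alt = p_alt * dnorm(.data$log2fc, object$alt$mu, object$alt$sd)
    ) |>
    tidyr::pivot_longer(c("null", "alt"), names_to = "component", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, fill = "grey80", colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "guide log2 fold-change (undifferentiated / differentiated)",
      y = "density", colour = NULL,
      title = "Guide enrichment mixture"
    ) +
    ggplot2::theme_minimal()
}

#' Plot cluster assignments on a 2-D embedding
#'
#' @param object A [cluster_features()] result.
#' @param embedding Optional tibble (`gene_id`, `tsne1`, `tsne2`), e.g. from
#'   [embed_tsne()]; computed on the cluster's gene order is the caller's
#'   responsibility.
#' @param ... Unused.
#' @return A ggplot (embedding scatter if given, else cluster-size bars).
#' @export
autoplot.lnc_cluster <- function(object, embedding = NULL, ...) {
  df <- tidy(object)
  if (!is.null(embedding)) {
    df <- inner_join(df, embedding, by = "gene_id")
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        x = .data$tsne1, y = .data$tsne2,
        colour = factor(.data$cluster), shape = .data$biotype
      )) +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::labs(colour = "cluster", title = "Feature-space embedding") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), fill = .data$biotype)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "cluster", y = "genes", title = "Cluster composition") +
    ggplot2::theme_minimal()
}

#' Bar chart of the filtering cascade survivor counts
#'
#' @param cascade A [filter_cascade()] result.
#' @return A ggplot.
#' @export
plot_filter_cascade <- function(cascade) {
  rep <- cascade$report |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$stage, y = .data$n_guides)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_guides), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "guides surviving", title = "sgRNA filtering cascade") +
    ggplot2::theme_minimal()
}

#' FDR versus effect size for TSS calls
#'
#' @param calls A classified per-TSS call tibble ([call_screen_hits()]).
#' @param fdr_hit Hit threshold line (default 0.1).
#' @return A ggplot.
#' @export
plot_tss_calls <- function(calls, fdr_hit = 0.1) {
  ggplot2::ggplot(
    filter(calls, !is.na(.data$effect_size)),
    ggplot2::aes(x = .data$effect_size, y = .data$fdr, colour = .data$is_hit)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = fdr_hit, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "effect size (mean of top-3 guide log2FC)", y = "global FDR",
      colour = "hit", title = "TSS-level screen calls"
    ) +
    ggplot2::theme_minimal()
}
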