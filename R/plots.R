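# ggplot2 displays for the main result types.

#' Box plot of an alpha-diversity index by group
#'
#' @param alpha output of [alpha_diversity()].
#' @param meta metadata tibble.
#' @param index "shannon", "simpson" or "chao1".
#' @return a ggplot.
#' @export
plot_alpha <- function(alpha, meta, index = "shannon") {
  dat <- alpha |>
    dplyr::left_join(meta, by = "sample_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data[[index]],
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5) +
    ggplot2::labs(x = NULL, y = index) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Ordination scatter of PCoA coordinates
#' @param x a `micronet_pcoa`.
#' @param meta optional metadata for colouring by group.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.micronet_pcoa <- function(x, meta = NULL, ...) {
  dat <- x$coordinates
  pct <- round(100 * x$proportion_explained[1:2], 1)
  if (!is.null(meta)) dat <- dplyr::left_join(dat, meta, by = "sample_id")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(meta)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
  p +
    ggplot2::labs(x = paste0("PCo1 (", pct[1], "%)"),
                  y = paste0("PCo2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Robustness curves of one or more stability reports
#'
#' @param reports named list of `micronet_stability` objects (names label the
#'   curves, e.g. cropping systems).
#' @return a ggplot of mean remaining connectivity (ribbon = +/- SD) against
#'   the removal fraction.
#' @export
plot_robustness <- function(reports) {
  dat <- purrr::imap_dfr(reports, function(r, nm) {
    r$robustness |> dplyr::mutate(network = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$removal_fraction, y = .data$mean,
                                    colour = .data$network, fill = .data$network)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of vertices removed",
                  y = "remaining connectivity") +
    ggplot2::theme_minimal()
}

#' Bar chart of LEfSe effect sizes
#' @param result output of [lda_effect_size()] or [lefse()].
#' @return a ggplot.
#' @export
plot_lefse <- function(result) {
  ggplot2::ggplot(
    result,
    ggplot2::aes(x = .data$effect_size,
                 y = stats::reorder(.data$feature, .data$effect_size),
                 fill = .data$enriched_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LDA effect size (log10)", y = NULL,
                  fill = "enriched in") +
    ggplot2::theme_minimal()
}

#' Co-occurrence network display
#' @param network a `micronet_network`.
#' @param seed layout seed.
#' @return a ggplot (Fruchterman-Reingold layout; positive edges solid,
#'   negative dashed).
#' @export
plot_network <- function(network, seed = 1) {
  g <- as_igraph(network)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- network$nodes |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2])
  edges <- network$edges |>
    dplyr::left_join(nodes |> dplyr::select("taxon_id", x0 = "x", y0 = "y"),
                     by = c(source = "taxon_id")) |>
    dplyr::left_join(nodes |> dplyr::select("taxon_id", x1 = "x", y1 = "y"),
                     by = c(target = "taxon_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linetype = .data$sign),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = .data$phylum)
    ) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::theme_void()
}
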