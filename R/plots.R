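#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a metaprofile
#'
#' @param x A `meta_profile`.
#' @param ... Unused.
#' @return The underlying tibble (rel_pos, value, n, masked).
#' @exportS3Method generics::tidy
tidy.meta_profile <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a metaprofile
#'
#' @param x A `meta_profile`.
#' @param core_halfwidth Offsets with `abs(rel_pos) <=` this are "core".
#' @param ... Unused.
#' @return Tibble with type, window, flank, n_features, core and flank
#'   means, and their ratio.
#' @exportS3Method generics::glance
glance.meta_profile <- function(x, core_halfwidth = 10, ...) {
  v <- as_tibble(x)
  core <- mean(v$value[abs(v$rel_pos) <= core_halfwidth], na.rm = TRUE)
  flank <- mean(v$value[abs(v$rel_pos) > core_halfwidth], na.rm = TRUE)
  tibble(type = attr(x, "type"), window = attr(x, "window"),
         flank_bp = attr(x, "flank"), n_features = attr(x, "n_features"),
         core_mean = core, flank_mean = flank,
         core_to_flank = core / flank)
}

#' @rdname tidy.meta_profile
#' @exportS3Method generics::tidy
tidy.inhibition_width <- function(x, ...) {
  tibble(left = x$left, right = x$right, width = x$width,
         baseline = x$baseline, threshold = x$threshold,
         flagged = x$flagged)
}

#' @rdname glance.meta_profile
#' @exportS3Method generics::glance
glance.inhibition_width <- function(x, ...) tidy.inhibition_width(x)

#' Plot a metaprofile
#'
#' Line plot of signal against motif- or TSS-relative position, with the
#' nucleosome overlay (if attached via [with_overlay()]) drawn as a gray
#' background area, in the style of aggregate damage/repair plots.
#'
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_profile <- function(object, ...) {
  df <- as_tibble(object)
  type <- attr(object, "type")
  ylab <- switch(type,
                 formation = "Normalized damage ratio (cellular / naked)",
                 remaining = "Fraction of remaining damage",
                 nucleosome = "Scaled nucleosome density",
                 "Signal")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_pos, y = .data$value))
  ov <- attr(object, "overlay")
  if (!is.null(ov)) {
    ovdf <- tibble(rel_pos = df$rel_pos,
                   value = ov * max(df$value, na.rm = TRUE))
    p <- p + ggplot2::geom_area(data = ovdf, fill = "gray80", alpha = 0.8)
  }
  p +
    ggplot2::geom_line(color = if (identical(type, "remaining")) "steelblue4" else "firebrick3",
                       linewidth = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", color = "gray40") +
    ggplot2::labs(x = "Position relative to feature midpoint (bp)", y = ylab) +
    ggplot2::theme_classic()
}

#' @export
plot.meta_profile <- function(x, ...) print(autoplot.meta_profile(x, ...))

#' Plot a gene heatmap
#'
#' Tile plot of per-gene remaining damage on the TSS-relative axis, rows
#' ordered by site-to-TSS distance (longest on top).
#'
#' @param object A `gene_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_heatmap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_pos, y = .data$gene_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "gray90",
                                  name = "Remaining\ndamage") +
    ggplot2::labs(x = "Position relative to TSS (bp)", y = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' @export
plot.gene_heatmap <- function(x, ...) print(autoplot.gene_heatmap(x, ...))
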