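SEVERITY_COLOURS <- c(
  "[0,15)" = "#f7e04b", "[15,30)" = "#f5b342",
  "[30,60)" = "#e07b27", "[60,180]" = "#c62828"
)

#' Plot an angular histogram
#'
#' @param torsions a `ts_torsions` tibble.
#' @param kind one angle kind name (see [angle_kinds()]).
#' @param bin_width histogram bin width in degrees (divisor of 360).
#' @return a ggplot object.
#' @export
plot_angle_histogram <- function(torsions, kind, bin_width = 15) {
  kind <- match.arg(kind, angle_kinds())
  h <- angle_histogram(torsions[[kind]], bin_width = bin_width,
                       range_start = if (kind == "pseudorotation") 0
                                     else -180)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = paste(kind, "(degrees)"), y = "residues") +
    ggplot2::theme_minimal()
}

#' Per-residue severity plot of a comparison
#'
#' Tile strip of per-residue MCQ severity along the target sequence, in
#' the standard heatmap bands (yellow < 15, orange bands, red > 60
#' degrees).
#'
#' @param object a `ts_comparison` from [compare_structures()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ts_comparison <- function(object, ...) {
  per <- object$per_residue
  ggplot2::ggplot(per, ggplot2::aes(x = .data$target_pos, y = 1,
                                    fill = .data$severity)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = SEVERITY_COLOURS,
                               na.value = "grey80", drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "target residue", y = NULL,
                  fill = "MCQ (degrees)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an MDS embedding
#'
#' @param object a `ts_mds` tibble from [mds_embed()].
#' @param clusters optional `ts_kmedoids` object used to colour points.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ts_mds <- function(object, clusters = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(clusters)) {
    df$cluster <- factor(clusters$assignment$cluster[
      match(df$label, clusters$assignment$label)
    ])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(clusters)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 2)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
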