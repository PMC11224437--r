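#' Plot a tree-space MDS embedding
#'
#' Scatter of the first two classical-MDS axes; an id matching
#' `highlight` (e.g. the species tree) is drawn in red.
#'
#' @param x An `"mds_embedding"` from [classical_mds()].
#' @param highlight Optional id to emphasize.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.mds_embedding <- function(x, highlight = NULL, ...) {
  df <- dplyr::mutate(x$coords,
                      role = ifelse(.data$id %in% highlight,
                                    "highlighted", "tree"))
  ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                   colour = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(tree = "grey30",
                                            highlighted = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2",
                  title = "Tree space (classical MDS of RF distances)") +
    ggplot2::theme_minimal()
}

#' @export
plot.mds_embedding <- function(x, ...) print(autoplot.mds_embedding(x, ...))

#' Plot phylogenetic-informativeness profiles
#'
#' @param x A `"pi_profile"` from [pi_profile()].
#' @param view `"total"` (dataset total PI over time), `"mean"` (mean PI
#'   per locus) or `"overlay"` (every locus curve).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pi_profile <- function(x, view = c("total", "mean", "overlay"), ...) {
  view <- match.arg(view)
  if (view == "overlay") {
    p <- ggplot2::ggplot(x$profile,
                         ggplot2::aes(.data$t, .data$pi,
                                      group = .data$locus_id)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::labs(y = "PI per locus")
  } else {
    ycol <- if (view == "total") "pi_total" else "pi_mean_locus"
    p <- ggplot2::ggplot(x$total,
                         ggplot2::aes(.data$t, .data[[ycol]])) +
      ggplot2::geom_line() +
      ggplot2::labs(y = if (view == "total") "Total PI" else "Mean PI per locus")
  }
  p + ggplot2::labs(x = "Time (reference-tree units)",
                    title = "Phylogenetic informativeness") +
    ggplot2::theme_minimal()
}

#' @export
plot.pi_profile <- function(x, ...) print(autoplot.pi_profile(x, ...))

#' Plot an occupancy ladder
#'
#' Locus counts and missing data across occupancy thresholds.
#'
#' @param ladder Tibble from [occupancy_ladder()].
#' @return A ggplot object.
#' @export
plot_occupancy_ladder <- function(ladder) {
  df <- tidyr::pivot_longer(
    dplyr::select(ladder, "min_occupancy_pct", "n_loci", "pct_missing"),
    cols = c("n_loci", "pct_missing"))
  ggplot2::ggplot(df, ggplot2::aes(.data$min_occupancy_pct, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "Minimum occupancy per locus (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
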