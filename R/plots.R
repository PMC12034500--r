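# ggplot2 displays for the main result types. These are quick diagnostic
# plots, not publication cartography.

#' Plot the CPI ranking
#'
#' @param scored A [build_scored_table()] tibble.
#' @param top Show only the `top` highest-priority species (default all).
#' @return A ggplot.
#' @export
plot_cpi_ranking <- function(scored, top = Inf) {
  dat <- scored[order(scored$cpi_rank), ]
  dat <- utils::head(dat, top)
  dat$species_name <- factor(dat$species_name, levels = rev(dat$species_name))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cpi, y = .data$species_name,
                                    fill = .data$genus)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Conservation Prioritization Index", y = NULL,
                  fill = "Genus") +
    ggplot2::theme_minimal()
}

#' @describeIn mfa Species map on the first two MFA dimensions, axes
#'   labelled with eigenvalues and percent variance.
#' @param object A `cpi_mfa` object (for `autoplot`).
#' @method autoplot cpi_mfa
#' @export
autoplot.cpi_mfa <- function(object, ...) {
  eg <- object$eig
  lab <- function(i) sprintf("Dim %d (%.2f, %.1f%%)", i, eg$eigenvalue[i],
                             eg$pct_variance[i])
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               label = .data$species_name)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

# x/y positions of leaves and internal nodes of an hclust tree
dendro_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- stats::setNames(seq_len(n), tree$order)
  node_x <- numeric(n - 1); node_y <- tree$height
  segs <- list()
  pos <- function(v) if (v < 0) c(leaf_x[[as.character(-v)]], 0) else
    c(node_x[v], node_y[v])
  for (i in seq_len(n - 1)) {
    a <- pos(tree$merge[i, 1]); b <- pos(tree$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[length(segs) + 1]] <- data.frame(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[i], node_y[i]), yend = c(node_y[i], node_y[i], b[2]))
  }
  list(segments = do.call(rbind, segs),
       nodes = data.frame(x = node_x, y = node_y, node = seq_len(n - 1)),
       leaves = data.frame(x = seq_len(n), label = tree$labels[tree$order]))
}

#' @describeIn multiscale_bootstrap_au Dendrogram with AU support (percent)
#'   printed at each internal node; nodes at or above `au_threshold` are
#'   highlighted.
#' @param object A `cpi_au` object (for `autoplot`).
#' @param au_threshold Highlight threshold (default 0.95).
#' @method autoplot cpi_au
#' @export
autoplot.cpi_au <- function(object, au_threshold = 0.95, ...) {
  dd <- dendro_segments(object$tree)
  dd$nodes$au <- object$support$au
  dd$nodes$strong <- dd$nodes$au >= au_threshold
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dd$segments,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_label(data = dd$nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = sprintf("%.0f", 100 * .data$au),
                                     colour = .data$strong), size = 2.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = dd$leaves$x, labels = dd$leaves$label) +
    ggplot2::labs(x = NULL, y = "Ward merge height (Gower)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a raster grid
#'
#' @param grid A [raster_grid()] (e.g. a richness map).
#' @param pa_layer Optional protected-area [geo_layer()] outlined on top.
#' @param proj Projection for `pa_layer` (required with `pa_layer`).
#' @return A ggplot of cell values with nodata blanked.
#' @export
plot_grid_map <- function(grid, pa_layer = NULL, proj = NULL) {
  ctr <- grid_cell_centers(grid)
  df <- expand.grid(y = ctr$y, x = ctr$x)
  df$value <- as.vector(grid$values)
  df$value[df$value == grid$nodata] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "value") +
    ggplot2::theme_minimal()
  if (!is.null(pa_layer)) {
    stopifnot(!is.null(proj))
    polys <- lapply(seq_len(nrow(pa_layer)), function(i) {
      r <- project_ring(proj, pa_layer$geometry[[i]][[1]][[1]])
      data.frame(x = r[, 1], y = r[, 2], id = i)
    })
    p <- p + ggplot2::geom_polygon(
      data = do.call(rbind, polys),
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      inherit.aes = FALSE, fill = NA, colour = "red")
  }
  p
}
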