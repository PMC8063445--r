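#' Heatmap of a logFC profile matrix
#'
#' Genes (rows) against conditions (columns), filled by logFC against the
#' healthy baseline; red over-expressed, blue under-expressed. When a
#' clustering is supplied, genes are ordered by the dendrogram and faceted by
#' cluster, mirroring the usual signature heatmap.
#'
#' @param profile Tibble from [build_profile()].
#' @param clusters Optional `txr_ward` from [ward_cluster()].
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profile, clusters = NULL) {
  long <- tidyr::pivot_longer(profile, -"gene_id",
                              names_to = "condition", values_to = "logFC")
  long$condition <- factor(long$condition, levels = names(profile)[-1])
  if (!is.null(clusters)) {
    ord <- if (!is.null(clusters$hclust)) {
      clusters$assignment$item_id[clusters$hclust$order]
    } else {
      clusters$assignment$item_id
    }
    long$gene_id <- factor(long$gene_id, levels = ord)
    long$cluster <- clusters$assignment$cluster[
      match(as.character(long$gene_id), clusters$assignment$item_id)]
  } else {
    long$gene_id <- factor(long$gene_id, levels = profile$gene_id)
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$condition,
                                          y = .data$gene_id,
                                          fill = .data$logFC)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182C", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "logFC vs WT") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(clusters)) {
    p <- p + ggplot2::facet_grid(cluster ~ ., scales = "free_y",
                                 space = "free_y")
  }
  p
}

#' @describeIn distance_report Dot-and-line plot of mean absolute distance
#'   from the healthy baseline per condition, one line per gene group
#'   ("all" plus each cluster).
#' @param object,x A `txr_distance` tibble.
#' @param ... Ignored.
#' @export
autoplot.txr_distance <- function(object, ...) {
  object$condition <- factor(object$condition, levels = unique(object$condition))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$condition,
                                       y = .data$mean_abs_logfc,
                                       colour = .data$gene_group,
                                       group = .data$gene_group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "mean |logFC| vs healthy baseline",
                  colour = "gene group") +
    ggplot2::theme_minimal()
}

#' @rdname distance_report
#' @export
plot.txr_distance <- function(x, ...) print(autoplot(x, ...))

#' @describeIn efficiency_scores Heatmap of efficiency scores (categories by
#'   treatments), restricted to filter-passing categories by default.
#' @param object,x A `txr_efficiency` tibble.
#' @param passing_only Show only filter-passing categories.
#' @param ... Ignored.
#' @export
autoplot.txr_efficiency <- function(object, passing_only = TRUE, ...) {
  df <- if (passing_only && any(object$passes_filter)) {
    dplyr::filter(object, .data$passes_filter)
  } else {
    object
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment, y = .data$category,
                                   fill = .data$efficiency_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#762A83", mid = "white",
                                  high = "#1B7837", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "efficiency\n(log10 ratio)") +
    ggplot2::theme_minimal()
}

#' @rdname efficiency_scores
#' @export
plot.txr_efficiency <- function(x, ...) print(autoplot(x, ...))

#' @describeIn ward_cluster Dendrogram of the agglomeration (merge heights in
#'   the ward.D2 convention).
#' @param object,x A `txr_ward`.
#' @param ... Ignored.
#' @export
autoplot.txr_ward <- function(object, ...) {
  tree <- object$hclust
  if (is.null(tree)) {
    abort_value("no dendrogram for a single-item clustering")
  }
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- list()
  coord <- function(id) {
    if (id < 0) c(x = unname(leaf_x[as.character(-id)]), h = 0)
    else c(x = node_x[id], h = node_h[id])
  }
  for (i in seq_len(nrow(tree$merge))) {
    a <- coord(tree$merge[i, 1])
    b <- coord(tree$merge[i, 2])
    node_x[i] <- mean(c(a["x"], b["x"]))
    segs[[i]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], b["h"], node_h[i]),
      yend = c(node_h[i], node_h[i], node_h[i]))
  }
  segs <- dplyr::bind_rows(segs)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = "items (dendrogram order)", y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @rdname ward_cluster
#' @export
plot.txr_ward <- function(x, ...) print(autoplot(x, ...))
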