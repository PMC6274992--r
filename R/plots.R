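# ggplot2 views of the result objects. These are reporting conveniences;
# all quantities they draw come from the computation functions.

#' Histogram of GSR indices per group
#'
#' Overlays the GSR-index distribution of each case group with the control
#' distribution — the view in which a second, low-GSR peak appears as
#' deregulated functions accumulate with disease progression.
#'
#' @param fpair A `gsr_functionome_pair`.
#' @param annotation Annotation tibble covering the case samples.
#' @param bins Number of histogram bins (default 40).
#' @return A ggplot object (facetted by case group).
#' @export
plot_gsr_histogram <- function(fpair, annotation, bins = 40) {
  long_vals <- function(fun, grp) {
    tidyr::pivot_longer(fun, -"sample_id", names_to = "set_id",
                        values_to = "gsr") |>
      dplyr::filter(!is.na(.data$gsr)) |>
      dplyr::mutate(cohort = grp)
  }
  ann <- annotation[match(fpair$case$sample_id, annotation$sample_id), ]
  case_long <- long_vals(fpair$case, "case") |>
    dplyr::mutate(group = ann$group[match(.data$sample_id,
                                          ann$sample_id)])
  ctrl_long <- long_vals(fpair$control, "control")
  groups <- intersect(default_group_labels(), unique(case_long$group))
  df <- dplyr::bind_rows(lapply(groups, function(g) {
    dplyr::bind_rows(
      dplyr::filter(case_long, .data$group == g),
      dplyr::mutate(ctrl_long, group = g))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gsr, fill = .data$cohort)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, alpha = 0.55,
                            position = "identity") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "GSR index", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn deregulation_table Dot plot of the most significant sets per
#'   group (case/control ratio against significance rank).
#' @param object A `gsr_dereg` tibble.
#' @param top_k Number of top-ranked sets shown per group (default 20).
#' @param ... Unused.
#' @method autoplot gsr_dereg
#' @export
autoplot.gsr_dereg <- function(object, top_k = 20, ...) {
  df <- dplyr::filter(object, !is.na(.data$rank), .data$rank <= top_k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "significance rank", y = "case/control GSR ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn cv_classify Boxplot of per-repeat CV metrics.
#' @param object A `gsr_cv` object.
#' @method autoplot gsr_cv
#' @export
autoplot.gsr_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_repeat, -"repeat_id",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s SVM, k = %d, %d repeats",
                                  object$task, object$k, object$repeats)) +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_group_profiles Dendrogram drawn with ggplot2.
#' @param object A `gsr_dendro` object.
#' @method autoplot gsr_dendro
#' @export
autoplot.gsr_dendro <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # Leaf x-positions in plotting order, then node coordinates bottom-up.
  leaf_x <- setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  pos <- function(id) {
    if (id < 0) c(leaf_x[[as.character(-id)]], 0) else
      c(node_x[id], node_y[id])
  }
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    segs[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[i]), yend = c(node_y[i], node_y[i],
                                             node_y[i]))
  }
  segs <- dplyr::bind_rows(segs)
  labs <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs, ggplot2::aes(x = .data$x, xend = .data$xend,
                                y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1) +
    ggplot2::scale_y_continuous("height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::expand_limits(y = -max(hc$height) / 4) +
    ggplot2::theme_minimal()
}

#' @describeIn common_deregulated Bar chart of Venn region sizes.
#' @param object A `gsr_venn` object.
#' @param ... Unused.
#' @method autoplot gsr_venn
#' @export
autoplot.gsr_venn <- function(object, ...) {
  df <- dplyr::arrange(object$counts, dplyr::desc(.data$n))
  df$signature <- factor(df$signature, levels = df$signature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "membership signature",
                  y = sprintf("sets (top-%d lists)", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
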