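# ggplot2 displays for the main result types. These are conveniences, not
# contracts: every figure can be rebuilt from the tidied tibbles.

#' Ternary diagram of three-part compositions
#'
#' @param data Wide composition table with exactly three parts.
#' @param parts Optional part column names (length 3).
#' @param colour Optional column (string) mapped to point colour.
#' @return A ggplot object.
#' @export
plot_ternary <- function(data, parts = NULL, colour = NULL) {
  parts <- part_cols(data, parts)
  pts <- ternary_coordinates(data, parts)
  tri <- tibble::tibble(
    x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0)
  )
  lab <- tibble::tibble(
    x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.05),
    part = parts
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$.x, y = .data$.y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y), inherit.aes = FALSE) +
    ggplot2::geom_text(data = lab, ggplot2::aes(x = .data$x, y = .data$y, label = .data$part), inherit.aes = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Biplot of a PCA fit
#'
#' Scores on the first two components with part rays overlaid. For clr-mode
#' fits this is the compositional biplot: links between ray vertices, not
#' the rays themselves, estimate pairwise log-ratio variances.
#'
#' @param object A [coda_pca] fit.
#' @param colour Optional id column mapped to point colour (e.g. `"task"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coda_pca <- function(object, colour = NULL, ...) {
  sc <- tidy(object, "scores")
  ld <- tidy(object, "loadings")
  scale_f <- max(abs(sc$PC1), abs(sc$PC2)) /
    max(abs(ld$PC1), abs(ld$PC2)) * 0.7
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour]])), alpha = 0.7) +
      ggplot2::labs(colour = colour)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_f, yend = .data$PC2 * scale_f),
      inherit.aes = FALSE, arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * scale_f * 1.08, y = .data$PC2 * scale_f * 1.08, label = .data$part),
      inherit.aes = FALSE, size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a variation matrix
#'
#' @param vm A [variation_matrix] object.
#' @return A ggplot object.
#' @export
plot_variation <- function(vm) {
  if (!inherits(vm, "variation_matrix")) {
    abort("`vm` must be a `variation_matrix` object.")
  }
  df <- tibble::as_tibble(vm$t, rownames = "part1") |>
    tidyr::pivot_longer(-"part1", names_to = "part2", values_to = "variance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$part1, y = .data$part2, fill = .data$variance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$variance, 2)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log-ratio\nvariance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Confusion-matrix heatmap of a cross-validation report
#'
#' @param object A [cross_validate()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      title = sprintf(
        "%s (%s), accuracy %.1f%%",
        toupper(object$kind), object$mode, 100 * object$accuracy
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of task mean compositions
#'
#' @param summaries Output of [summarize_tasks()].
#' @param track `"compositional"` (percent shares) or `"classical"` (mean
#'   ms).
#' @return A ggplot object.
#' @export
plot_task_means <- function(summaries, track = c("compositional", "classical")) {
  track <- match.arg(track)
  df <- task_mean_table(summaries)
  yvar <- if (track == "compositional") "mean_pct" else "mean_ms"
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$task), y = .data[[yvar]], fill = .data$aoi
  )) +
    ggplot2::geom_col(position = if (track == "compositional") "stack" else "dodge") +
    ggplot2::labs(
      x = "task",
      y = if (track == "compositional") "mean share (%)" else "mean TDoF (ms)",
      fill = "AOI"
    ) +
    ggplot2::theme_minimal()
}
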