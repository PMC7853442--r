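# Figure rendering: grouped-bar histograms with SE bars, approach heat maps.
# Figures are derived artifacts; every plotted number lives in a CSV sidecar.

#' Grouped-bar class histogram with standard-error bars
#'
#' @param class_means element of a bundle's `class_means`: list with `a` and
#'   `b` data frames from [class_mean_histogram()].
#' @param labels class display labels.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_class_histograms <- function(class_means, labels = c("A", "B"),
                                  title = NULL) {
  a <- class_means$a; a$class <- labels[1]
  b <- class_means$b; b$class <- labels[2]
  df <- rbind(a, b)
  df$bin <- factor(df$bin, levels = unique(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = "bin (upper edge)", y = "normalized frequency",
                  fill = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heat map of a directed-pair approach matrix
#'
#' Warmer cells mean the row individual approached the column individual more
#' often (within the selected angle bin and look-back window).
#'
#' @param m matrix from [approach_matrix()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_approach_matrix <- function(m, title = NULL) {
  df <- expand.grid(approacher = rownames(m), target = colnames(m),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$approacher,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "navy", high = "orangered",
                                 limits = c(0, max(m, 1e-12))) +
    ggplot2::labs(x = "target", y = "approacher", fill = "freq",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Render all figures for a report bundle
#'
#' Writes one grouped-bar histogram per index and one heat map per session,
#' each next to the CSV sidecar already written by [write_bundle()]. Empty
#' tables are skipped with a warning.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory.
#' @param width,height figure size in inches.
#' @return character vector of written figure paths, invisibly.
#' @export
render_outputs <- function(bundle, out_dir, width = 8, height = 4.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (kind in names(bundle$class_means)) {
    cm <- bundle$class_means[[kind]]
    if (nrow(cm$a) == 0L) {
      warning("empty comparison table for ", kind, "; figure skipped")
      next
    }
    p <- plot_class_histograms(cm, labels = bundle$config$class_labels,
                               title = kind)
    f <- file.path(out_dir, paste0("hist_", kind, ".png"))
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 150)
    written <- c(written, f)
  }
  for (sname in names(bundle$matrices)) {
    p <- plot_approach_matrix(bundle$matrices[[sname]], title = sname)
    f <- file.path(out_dir, paste0("approach_matrix_", sname, ".png"))
    ggplot2::ggsave(f, p, width = 5.5, height = 4.5, dpi = 150)
    written <- c(written, f)
  }
  invisible(written)
}
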