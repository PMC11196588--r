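# ggplot2 autoplot methods for the main result types.

#' Plot an Evanno delta-K curve
#'
#' @param object an `evanno_dk` table from [evanno_delta_k()].
#' @param ... unused.
#' @return A ggplot: delta-K against K, with the selected K highlighted.
#' @method autoplot evanno_dk
#' @export
autoplot.evanno_dk <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$delta_k))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
  kb <- best_k(object)
  if (!is.na(kb)) {
    p <- p + ggplot2::geom_vline(xintercept = kb, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot PCA coordinates
#'
#' @param object a `pca_result`.
#' @param groups optional per-sample group labels (vector, named vector
#'   or `sample`/`group` tibble) used for colouring.
#' @param ... unused.
#' @return A ggplot of PC1 vs PC2 with explained-variance axis labels.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    if (inherits(groups, "data.frame")) {
      df <- dplyr::left_join(df, groups, by = "sample")
    } else {
      key <- names(groups) %||% df$sample
      df$group <- groups[match(df$sample, key)]
    }
    df$group <- factor(df$group)
  }
  mapping <- if (is.null(groups)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", object$explained[1]),
      y = sprintf("PC2 (%.2f%%)", object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a membership barplot for an admixture fit
#'
#' Samples are ordered by assigned group and decreasing membership, the
#' standard STRUCTURE-style layout.
#'
#' @param object an `admixture_fit`.
#' @param ... unused.
#' @return A stacked-bar ggplot of ancestry proportions.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, ...) {
  rep <- structure_report(object)
  long <- rep |>
    dplyr::mutate(sample = factor(.data$sample, levels = .data$sample)) |>
    tidyr::pivot_longer(dplyr::starts_with("Q"), names_to = "cluster",
                        values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a core-collection ratio sweep
#'
#' @param object a `ratio_sweep` from [sweep_ratios()].
#' @param ... unused.
#' @return A ggplot of He / PIC / pi against sampling ratio per group.
#' @method autoplot ratio_sweep
#' @export
autoplot.ratio_sweep <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("he", "pic", "pi"), names_to = "statistic",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio_pct, y = .data$value,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "Sampling ratio (%)", y = "Mean statistic") +
    ggplot2::theme_minimal()
}
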