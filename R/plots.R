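#' Heatmap of a kinship matrix
#'
#' @param object A `kinship_matrix`.
#' @param ... Unused.
#' @return A ggplot: individuals on both axes (panel order), fill = kinship.
#' @exportS3Method ggplot2::autoplot
autoplot.kinship_matrix <- function(object, ...) {
  K <- object$entries
  df <- tibble(
    id1 = factor(rep(rownames(K), ncol(K)), levels = rownames(K)),
    id2 = factor(rep(colnames(K), each = nrow(K)), levels = rownames(K)),
    kinship = as.vector(K))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id2, y = .data$id1,
                                   fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s kinship (reference: %s)",
                                  object$family, object$reference)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Population-specific F-statistics
#'
#' @param object An [as_fst()] result.
#' @param ... Unused.
#' @return A ggplot: per-population `F_SB^i` bars with the overall `F_SB`
#'   as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.as_fst <- function(object, ...) {
  df <- dplyr::filter(object$by_pop, .data$statistic == "F_SB_i")
  overall <- object$overall$value[object$overall$statistic == "F_SB"]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = overall, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "population", y = expression(hat(F)[SB]^i),
                  title = sprintf("Population-specific structure (overall %.4f)",
                                  overall)) +
    ggplot2::theme_minimal()
}

#' Bootstrap replicate distribution
#'
#' @param object A [block_bootstrap()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot histogram of replicates with the point estimate (solid)
#'   and percentile interval (dashed) marked.
#' @exportS3Method ggplot2::autoplot
autoplot.block_bootstrap <- function(object, bins = 40, ...) {
  df <- tibble(replicate = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dashed") +
    ggplot2::labs(x = "bootstrap replicate", y = "count",
                  title = sprintf("%d block-bootstrap replicates (blocks of %d)",
                                  length(object$replicates), object$block_size)) +
    ggplot2::theme_minimal()
}
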