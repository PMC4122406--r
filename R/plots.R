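#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_step
#'   geom_hline geom_vline scale_fill_gradient labs theme_minimal facet_wrap
NULL

#' Consensus-matrix heat map
#'
#' Samples ordered by the final dendrogram; block structure reveals stable
#' subgroups.
#'
#' @param object A `chcfs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chcfs_result <- function(object, ...) {
  C <- object$consensus$consensus
  ord <- stats::hclust(stats::as.dist(1 - C), method = "average")$order
  ids <- rownames(C)[ord]
  df <- as_tibble(C, rownames = "sample_1") |>
    tidyr::pivot_longer(-"sample_1", names_to = "sample_2",
                        values_to = "consensus") |>
    dplyr::mutate(sample_1 = factor(.data$sample_1, ids),
                  sample_2 = factor(.data$sample_2, ids))
  ggplot(df, aes(x = .data$sample_1, y = .data$sample_2,
                 fill = .data$consensus)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#2166AC", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "consensus",
         title = sprintf("Consensus matrix (k = %d)", object$k)) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Volcano plot of differential methylation
#'
#' @param diff A `diffmeth_result`.
#' @return A ggplot of delta-beta versus -log10 p with significant probes
#'   highlighted.
#' @export
plot_volcano <- function(diff) {
  df <- volcano_table(diff)
  ggplot(df, aes(x = .data$delta_beta, y = .data$neg_log10_p,
                 colour = .data$significant)) +
    geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    geom_vline(xintercept = c(-attr(diff, "min_delta"),
                              attr(diff, "min_delta")),
               linetype = "dashed", colour = "grey40") +
    labs(x = expression(Delta * beta ~ "(tumor - adjacent)"),
         y = expression(-log[10] ~ p)) +
    theme_minimal()
}

#' Starburst plot of joint methylation/expression significance
#'
#' @param integrated An `integrated_genes` tibble.
#' @return A ggplot with signed -log10 q on both axes and quadrants
#'   coloured.
#' @export
plot_starburst <- function(integrated) {
  df <- starburst_table(integrated)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$quadrant)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = expression(signed ~ -log[10] ~ q[methylation]),
         y = expression(signed ~ -log[10] ~ q[expression])) +
    theme_minimal()
}

#' Kaplan-Meier curves by subgroup
#'
#' @param records Survival records with `time`, `event`, `group`.
#' @return A ggplot of the product-limit step curves.
#' @export
plot_km <- function(records) {
  km <- km_estimate(records)
  start <- km |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start, km[, c("group", "time", "surv")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time (months)", y = "Survival probability") +
    theme_minimal()
}

#' Before/after PCA of a batch-correction run
#'
#' @param report Output of [quality_batch_report()].
#' @return A faceted ggplot of the first two principal components.
#' @export
plot_batch_pca <- function(report) {
  ggplot(report$pca, aes(x = .data$PC1, y = .data$PC2,
                         colour = .data$platform)) +
    geom_point() +
    facet_wrap(~factor(.data$stage, c("before", "after"))) +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot
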