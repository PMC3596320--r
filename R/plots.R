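# ggplot2 views of the main result types. These are working plots for the
# analyst, not publication figures.

#' @method autoplot chase_dataset
#' @export
autoplot.chase_dataset <- function(object, genes = NULL, ...) {
  d <- object$intensities
  if (is.null(genes)) genes <- head(unique(d$gene), 12)
  d |>
    dplyr::filter(.data$gene %in% genes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_min,
                                 y = log(.data$intensity),
                                 colour = .data$batch)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time after arrest (min)", y = "ln intensity",
                  colour = "batch")
}

#' Half-life distribution with rolling average
#'
#' Histogram of reliable half-lives overlaid with the rolling average over
#' the sorted values (the smoothed tendency line used when comparing
#' distributions across growth rates).
#'
#' @param fits A fit tibble from [fit_decay()], or a list of them named by
#'   condition.
#' @param bin_width Histogram bin width (minutes).
#' @return A ggplot object.
#' @export
plot_halflife_distribution <- function(fits, bin_width = 2) {
  if (is.data.frame(fits)) fits <- list(all = fits)
  th <- purrr::imap(fits, function(f, lab) {
    tibble::tibble(condition = lab,
                   t_half = f$t_half_min[f$status == "reliable"])
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$t_half))
  ggplot2::ggplot(th, ggplot2::aes(x = .data$t_half,
                                   fill = .data$condition)) +
    ggplot2::geom_histogram(binwidth = bin_width, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(x = "half-life (min)", y = "genes", fill = NULL)
}

#' Double-logarithmic regulation plot
#'
#' The change in decay constant against the change in mRNA level between two
#' conditions, one point per gene, coloured by regulation bin. The opposite
#' slope of a gene's displacement is its degradation regulation coefficient
#' rho_d: points on the x-axis are purely transcriptional (II), the
#' diagonal d_ln_k = -d_ln_mrna is purely degradational (I).
#'
#' @param results Output of [regulation_coefficients()].
#' @return A ggplot object.
#' @export
plot_regulation <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$d_ln_mrna,
                                        y = .data$d_ln_k,
                                        colour = .data$bin)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(slope = -1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(Delta ~ "ln [mRNA]"),
                  y = expression(Delta ~ "ln k"), colour = NULL)
}

#' @method autoplot ward_clustering
#' @export
autoplot.ward_clustering <- function(object, confidence = 0.05, ...) {
  cluster_summary(object, confidence = confidence) |>
    dplyr::mutate(cluster = factor(.data$cluster)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$condition, y = .data$mean,
                                 group = .data$cluster,
                                 colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.1) +
    ggplot2::labs(x = "condition", y = "mean half-life (min)",
                  colour = "cluster")
}

#' @method autoplot covmodel_fit
#' @export
autoplot.covmodel_fit <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$estimate,
                                 y = stats::reorder(.data$term,
                                                    .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2
    ) +
    ggplot2::labs(x = "coefficient (response: ln half-life)", y = NULL)
}
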