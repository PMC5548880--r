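#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of posterior hazard ratios versus the reference
#'
#' One row per regimen, posterior median HR with equal-tailed credible
#' interval, faceted by endpoint; the dashed line at 1 marks the reference
#' and the dotted line the clinically-meaningful threshold.
#'
#' @param object An `nma_fit`.
#' @param level Credible level.
#' @param thresholds A [decision_thresholds()] (drawn as the dotted
#'   reference line).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nma_fit <- function(object, level = 0.95,
                             thresholds = decision_thresholds(), ...) {
  tab <- summarize_nma(object, level = level, thresholds = thresholds)
  tab <- tab[!is.na(tab$hr_median) & tab$regimen != object$network$reference, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hr_median,
                                    y = stats::reorder(.data$regimen,
                                                       .data$sucra))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = thresholds$hr_max, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$cri_low,
                                          xmax = .data$cri_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(x = sprintf("Hazard ratio vs %s (%g%% CrI, log scale)",
                              object$network$reference, 100 * level),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the geometry of an evidence network
#'
#' Regimens on a circle, one edge per direct comparison, edge width
#' proportional to the number of estimates informing the contrast.
#'
#' @param object An `hr_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_network <- function(object, ...) {
  regs <- object$regimens
  k <- length(regs)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- tibble::tibble(regimen = regs, x = cos(ang), y = sin(ang),
                          is_ref = regs == object$reference)
  edges <- dplyr::count(object$estimates, .data$regimen_a, .data$regimen_b)
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[, 1:3], xa = "x", ya = "y"),
                            by = c(regimen_a = "regimen"))
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[, 1:3], xb = "x", yb = "y"),
                            by = c(regimen_b = "regimen"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$n),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, colour = .data$is_ref),
                        size = 4, show.legend = FALSE) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$regimen)) +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' Bar chart of SUCRA values for one endpoint
#'
#' @param fit An `nma_fit`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A ggplot object.
#' @export
plot_sucra <- function(fit, endpoint) {
  su <- sucra(rank_probabilities(fit, endpoint))
  tab <- tibble::tibble(regimen = names(su), sucra = unname(su))
  ggplot2::ggplot(tab, ggplot2::aes(stats::reorder(.data$regimen, .data$sucra),
                                    .data$sucra)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.1f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = paste0("SUCRA (", endpoint, ")")) +
    ggplot2::theme_minimal()
}

#' Heatmap of posterior rank probabilities
#'
#' @inheritParams plot_sucra
#' @return A ggplot object.
#' @export
plot_ranks <- function(fit, endpoint) {
  rp <- rank_probabilities(fit, endpoint)
  colnames(rp) <- seq_len(ncol(rp))
  tab <- tibble::as_tibble(rp, rownames = "regimen")
  tab <- tidyr::pivot_longer(tab, -"regimen", names_to = "rank",
                             values_to = "probability")
  tab$rank <- as.integer(tab$rank)
  ggplot2::ggplot(tab, ggplot2::aes(.data$rank, .data$regimen,
                                    fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = paste0("Rank (1 = best, ", endpoint, ")"), y = NULL) +
    ggplot2::theme_minimal()
}
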