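#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A [psa()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x) {
  stopifnot(inherits(x, "btc_psa"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x$ceac, ggplot2::aes(x = wtp, y = prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$wtp, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(durvalumab + chemotherapy cost-effective)") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Shows the `n_top` parameters with the widest ICER span around the
#' base-case ICER.
#'
#' @param x An [owsa()] result.
#' @param n_top Number of parameters displayed.
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, n_top = 10) {
  stopifnot(inherits(x, "btc_owsa"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- utils::head(as.data.frame(x), n_top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(x, "icer_base")
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       yend = parameter), linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter plot
#'
#' Monte-Carlo samples on the incremental cost vs incremental QALY plane
#' with the willingness-to-pay line.
#'
#' @param x A [psa()] result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(x) {
  stopifnot(inherits(x, "btc_psa"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x$samples,
                  ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = x$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)") +
    ggplot2::theme_minimal()
}

#' @importFrom utils packageVersion
NULL

utils::globalVariables(c("wtp", "prob_ce", "parameter", "icer_low",
  "icer_high", "delta_qaly", "delta_cost"))
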