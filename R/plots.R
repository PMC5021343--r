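#' Plot a current trace
#'
#' Current versus time with the agonist application window shaded.
#'
#' @param object a `current_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot current_trace
#' @export
autoplot.current_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = "Current (pA)") +
    ggplot2::theme_classic()
  proto <- attr(object, "protocol")
  if (!is.null(proto)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = proto$pulse_start,
      xmax = proto$pulse_start + proto$pulse_duration,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue")
  }
  p
}

#' Plot a Hill concentration-response fit
#'
#' Observed responses (if supplied) and the fitted logistic on a
#' log-concentration axis, with the EC50 marked.
#'
#' @param object a `hill_fit`.
#' @param data optional data frame with `concentration_M` and `response`
#'   columns to overlay as points.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, data = NULL, ...) {
  rng <- if (!is.null(data)) log10(range(data$concentration_M)) else
    log10(object$ec50) + c(-3, 3)
  grid <- tibble(lc = seq(rng[1] - 0.5, rng[2] + 0.5, length.out = 200))
  grid$response <- object$bottom + (object$top - object$bottom) /
    (1 + 10^((log10(object$ec50) - grid$lc) * object$hill_slope))
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$lc, .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$ec50), linetype = 3) +
    ggplot2::labs(x = "log10 [GABA] (M)", y = "Normalized response") +
    ggplot2::theme_classic()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = mutate(as_tibble(data), lc = log10(.data$concentration_M)),
      ggplot2::aes(.data$lc, .data$response), alpha = 0.6)
  }
  p
}

#' Plot a perturbation report
#'
#' Mean per-element side-chain and secondary-structure RMS deviations with
#' the flagging threshold.
#'
#' @param object a `perturbation_report` from [ensemble_rms()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot perturbation_report
#' @export
autoplot.perturbation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("chain", "element", "sidechain_rms",
                        "secondary_structure_rms")],
    cols = c("sidechain_rms", "secondary_structure_rms"),
    names_to = "measure", values_to = "rms")
  ggplot2::ggplot(long, ggplot2::aes(.data$element, .data$rms,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = NULL, y = "Mean RMS deviation (Å)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the domain distribution of a variant catalog
#'
#' @param records variant records with a `domain` column.
#' @return A ggplot object.
#' @export
plot_domain_distribution <- function(records) {
  dd <- domain_distribution(records)
  ggplot2::ggplot(dd, ggplot2::aes(.data$domain, .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Receptor domain", y = "Variants") +
    ggplot2::theme_classic()
}
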