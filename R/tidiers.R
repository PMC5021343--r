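#' Tidy an exponential fit
#'
#' @param x an `exp_fit` from [fit_exponentials()].
#' @param ... unused.
#' @return A tibble with one row per component: `term`, `a`, `tau`.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  if (!nrow(x$components)) {
    return(tibble(term = character(), a = numeric(), tau = numeric()))
  }
  mutate(x$components, term = paste0("component", dplyr::row_number()),
         .before = 1)
}

#' @rdname tidy.exp_fit
#' @return For `glance()`: a one-row model summary with the component count,
#'   weighted tau, offset, SSR and segment bounds.
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         weighted_tau = if (nrow(x$components)) weighted_tau(x) else NA_real_,
         offset = x$offset, ssr = x$ssr, n_points = x$n_points,
         direction = x$direction, no_decay = x$no_decay,
         segment_start = x$segment[1], segment_end = x$segment[2])
}

#' Tidy a Hill concentration-response fit
#'
#' @param x a `hill_fit` from [fit_hill()].
#' @param ... unused.
#' @return A tibble of parameter estimates.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ec50", "hill_slope", "top", "bottom"),
         estimate = c(x$ec50, x$hill_slope, x$top, x$bottom))
}

#' @rdname tidy.hill_fit
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, hill_slope = x$hill_slope, top = x$top,
         bottom = x$bottom, ssr = x$ssr, n_points = x$n_points)
}

#' Tidy a group comparison
#'
#' @param x a `group_comparison` from [compare_to_wt()].
#' @param ... unused.
#' @return The per-comparison tibble (group, mean difference, statistic,
#'   p-value, significance flag).
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "group_comparison")
  out
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = attr(x, "test"), n_comparisons = nrow(x),
         wt_mean = attr(x, "wt_mean"), wt_n = attr(x, "wt_n"),
         anova_p = attr(x, "anova_p"), alpha = attr(x, "alpha"),
         n_significant = sum(x$significant))
}
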