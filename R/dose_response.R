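#' Fit a Hill (four-parameter logistic) concentration-response curve
#'
#' Fits `r(c) = bottom + (top - bottom) / (1 + 10^((log10(EC50) - log10(c)) *
#' slope))` by deterministic multi-start Levenberg-Marquardt least squares in
#' log-concentration. Responses are expected normalized to the saturating
#' response of the same curve (so `top` is near 1), but the normalization is
#' not enforced.
#'
#' @param data either a data frame with columns `concentration_M` and
#'   `response`, or a numeric vector of concentrations (molar) with the
#'   responses passed as `response`.
#' @param response numeric responses when `data` is a vector.
#' @return An object of class `hill_fit` with `ec50` (molar), `hill_slope`,
#'   `top`, `bottom`, `ssr` and `n_points`.
#' @seealso [logec50_ratio()], [fold_change()], [tidy.hill_fit()]
#' @export
#' @examples
#' conc <- 10^seq(-8, -4, by = 0.5)
#' resp <- 1 / (1 + (2e-7 / conc))
#' fit_hill(conc, resp)$ec50
fit_hill <- function(data, response = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("concentration_M", "response") %in% names(data)))
    conc <- data$concentration_M
    resp <- data$response
  } else {
    conc <- data
    resp <- response
  }
  if (length(conc) != length(resp)) {
    abort("concentrations and responses must have equal length",
          class = "gabrisk_bad_input")
  }
  ok <- is.finite(conc) & is.finite(resp) & conc > 0
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc)) < 4L) {
    abort("need >= 4 distinct positive concentrations",
          class = "gabrisk_bad_input")
  }
  lc <- log10(conc)
  dat <- list(lc = lc, y = resp)
  rng <- range(lc)
  starts <- expand.grid(lec50 = seq(rng[1], rng[2], length.out = 5),
                        slope = c(0.5, 1, 2))
  top0 <- max(resp); bot0 <- min(resp)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((lec50 - lc) * slope)),
        data = dat,
        start = list(top = top0, bottom = bot0,
                     lec50 = starts$lec50[i], slope = starts$slope[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    if (!all(is.finite(cf)) || cf[["top"]] <= cf[["bottom"]] || cf[["slope"]] <= 0) next
    ssr <- sum(resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(ec50 = 10^cf[["lec50"]], hill_slope = cf[["slope"]],
                   top = cf[["top"]], bottom = cf[["bottom"]],
                   ssr = ssr, n_points = length(resp))
    }
  }
  if (is.null(best)) {
    abort(paste0("Hill fit failed to converge from every start (",
                 length(resp), " points spanning ",
                 signif(min(conc), 3), "-", signif(max(conc), 3), " M); ",
                 "is the response monotone in concentration?"),
          class = "gabrisk_fit_failure")
  }
  structure(best, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g M, slope %.3g, top %.3g, bottom %.3g (SSR %.3g, n = %d)\n",
              x$ec50, x$hill_slope, x$top, x$bottom, x$ssr, x$n_points))
  invisible(x)
}

#' Variant / wild-type LogEC50 change ratio
#'
#' `log10(ec50_variant) / log10(ec50_wt)` with both EC50s expressed in molar.
#' For sub-molar EC50s (negative logs) a rightward potency shift of the
#' variant yields a ratio below 1: ratio < 1 is read as loss-of-function,
#' ratio > 1 as gain-of-function. The molar scale matters: a 10-fold EC50
#' increase from 0.2 uM gives a ratio of ~0.85, the magnitude the printed
#' per-cell ratios take; expressing the EC50s in other units would change the
#' ratio.
#'
#' @param ec50_variant,ec50_wt EC50s in molar; both > 0 and different from
#'   1 M (log10(1) = 0 makes the ratio undefined).
#' @return The dimensionless ratio.
#' @export
#' @examples
#' logec50_ratio(2e-6, 2e-7) # ~0.851, loss-of-function
logec50_ratio <- function(ec50_variant, ec50_wt) {
  if (any(c(ec50_variant, ec50_wt) <= 0)) {
    abort("EC50s must be > 0 (molar)", class = "gabrisk_bad_input")
  }
  if (any(ec50_variant == 1) || any(ec50_wt == 1)) {
    abort("EC50 of exactly 1 M makes the log ratio undefined",
          class = "gabrisk_bad_input")
  }
  log10(ec50_variant) / log10(ec50_wt)
}

#' EC50 fold change
#'
#' `ec50_variant / ec50_wt`; values above 1 are rightward (loss-of-potency)
#' shifts.
#'
#' @inheritParams logec50_ratio
#' @return The fold change.
#' @export
#' @examples
#' fold_change(2e-6, 2e-7) # 10
fold_change <- function(ec50_variant, ec50_wt) {
  if (any(c(ec50_variant, ec50_wt) <= 0)) {
    abort("EC50s must be > 0", class = "gabrisk_bad_input")
  }
  ec50_variant / ec50_wt
}
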