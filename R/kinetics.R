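#' Fit a sum of exponentials to a current segment
#'
#' Fits `y(t) = sum_n a_n * exp(-t / tau_n) + C` to a segment of a trace by
#' Levenberg-Marquardt least squares, growing the number of components from
#' one up to `max_components` and retaining an extra component only when the
#' extra-sum-of-squares F test on the residuals improves the fit at
#' `alpha_F`. Initialization is multi-start (log-spaced time-constant seeds
#' over the segment, amplitudes solved by linear least squares); among
#' converged starts the lowest SSR wins, and the F test breaks ties toward
#' fewer components. The fit is deterministic for fixed inputs.
#'
#' @param trace a [new_current_trace()] tibble (or any data frame with
#'   `time_ms` and `current_pA`).
#' @param segment numeric `c(start, end)` in ms, inside the trace. Defaults
#'   to the whole trace.
#' @param direction `"deactivation"` or `"activation"`; recorded on the fit
#'   (segment selection is up to the caller or [fit_gating()]).
#' @param max_components maximum number of exponential components (<= 4).
#' @param alpha_F significance level of the extra-sum-of-squares F test.
#' @param n_starts number of multi-start initializations per component count.
#' @param min_tau_ratio identifiability guard: a richer model is accepted
#'   only when its adjacent time constants are separated by at least this
#'   factor. Multi-exponential fits with closer time constants are
#'   ill-conditioned (the components trade amplitude freely), so such fits
#'   are treated as degenerate rather than as evidence for an extra
#'   component. Set to 1 to disable.
#' @return An object of class `exp_fit`: components (tibble of `a`, `tau`
#'   sorted by ascending `tau`), `offset`, `ssr`, `n_points`, `segment`,
#'   `direction`, and `no_decay` (`TRUE` when no component was accepted over
#'   the flat offset-only model).
#' @seealso [weighted_tau()], [tidy.exp_fit()], [fit_gating()]
#' @export
#' @examples
#' t <- seq(0, 300, by = 0.1)
#' tr <- new_current_trace(t, 5 * exp(-t / 10))
#' fit <- fit_exponentials(tr)
#' tidy(fit)
fit_exponentials <- function(trace, segment = NULL,
                             direction = c("deactivation", "activation"),
                             max_components = 4, alpha_F = 0.05,
                             n_starts = 8, min_tau_ratio = 2) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(trace), all(c("time_ms", "current_pA") %in% names(trace)))
  if (max_components < 1 || max_components > 4) {
    abort("`max_components` must be between 1 and 4", class = "gabrisk_bad_input")
  }
  if (is.null(segment)) segment <- range(trace$time_ms)
  if (segment[1] < min(trace$time_ms) - 1e-9 || segment[2] > max(trace$time_ms) + 1e-9) {
    abort("`segment` must lie inside the trace", class = "gabrisk_bad_input")
  }
  keep <- trace$time_ms >= segment[1] & trace$time_ms <= segment[2]
  tt <- trace$time_ms[keep] - segment[1]
  yy <- trace$current_pA[keep]
  n <- length(yy)
  if (n < 12L) {
    abort("segment too short: need >= 10x more points than free parameters",
          class = "gabrisk_bad_input")
  }
  # the 10x points-per-parameter rule gates model growth; the smallest
  # (single-component) model is always attempted so short activation
  # windows at 10 kHz remain fittable
  k_cap <- max(1L, min(max_components, floor((n / 10 - 1) / 2)))

  selected <- list(k = 0L, a = numeric(), tau = numeric(),
                   offset = mean(yy), ssr = sum((yy - mean(yy))^2))
  k <- 0L
  while (k < k_cap) {
    cand <- fit_k_exponentials(tt, yy, k + 1L, n_starts,
                               prev = if (k > 0L) selected)
    if (is.null(cand)) {
      if (k == 0L && var(yy) > 0) {
        abort("exponential fit failed to converge at every start",
              class = "gabrisk_fit_failure")
      }
      break
    }
    if (length(cand$tau) > 1L) {
      ratios <- exp(abs(diff(sort(log(cand$tau)))))
      if (any(ratios < min_tau_ratio)) break # degenerate tau split
    }
    # extra-sum-of-squares F test: 2 extra free parameters per component
    p_new <- 2L * (k + 1L) + 1L
    df2 <- n - p_new
    ss_old <- selected$ssr
    ss_new <- cand$ssr
    if (ss_new >= ss_old || df2 <= 0) break
    f_stat <- ((ss_old - ss_new) / 2) / (ss_new / df2)
    p_val <- pf(f_stat, 2, df2, lower.tail = FALSE)
    if (is.finite(p_val) && p_val < alpha_F) {
      selected <- cand
      k <- k + 1L
      # a machine-perfect fit leaves only rounding error; F comparisons on
      # it are meaningless, so stop growing
      if (selected$ssr <= 1e-20 * sum(yy^2)) break
    } else {
      break
    }
  }

  ord <- order(selected$tau)
  structure(
    list(components = tibble(a = selected$a[ord], tau = selected$tau[ord]),
         offset = selected$offset,
         ssr = selected$ssr,
         n_points = n,
         segment = segment,
         direction = direction,
         alpha_F = alpha_F,
         no_decay = selected$k == 0L),
    class = "exp_fit"
  )
}

# Best k-component fit over deterministic multi-starts; NULL if none
# converge. The segments handled here are monotone relaxations (rise to a
# peak or decay from it), so all component amplitudes are constrained to the
# sign of the dominant decay; this keeps tiny opposite-sign components from
# chasing noise. `prev` (the accepted (k-1)-component solution) seeds
# warm-start continuations alongside the sliding log-spaced grid.
fit_k_exponentials <- function(tt, yy, k, n_starts, prev = NULL) {
  t_max <- max(tt)
  dt <- min(diff(sort(unique(tt))))
  lo <- max(dt / 2, 1e-3)
  hi <- max(t_max, lo * 10)
  n_edge <- max(2L, ceiling(length(yy) * 0.05))
  sgn <- sign(mean(head(yy, n_edge)) - mean(tail(yy, n_edge)))
  if (sgn == 0) sgn <- 1
  y2 <- sgn * yy # fit with all amplitudes >= 0, flip back afterwards

  lrange <- c(log(lo * 2), log(hi / 2))
  tau_grid <- exp(seq(lrange[1], lrange[2], length.out = n_starts))
  starts <- lapply(seq_len(n_starts), function(s) {
    f_s <- (s - 0.5) / n_starts
    exp(lrange[1] + (seq_len(k) - 1 + f_s) / k * diff(lrange))
  })
  if (!is.null(prev) && length(prev$tau) == k - 1L) {
    # continuation: previous taus plus one new seed from the grid
    starts <- c(starts, lapply(tau_grid, function(tn) sort(c(prev$tau, tn))))
  }

  best <- NULL
  form <- exp_sum_formula(k)
  lower <- c(rep(-Inf, k), rep(0, k), -Inf)
  for (taus0 in starts) {
    taus0 <- pmin(pmax(taus0, lo), hi)
    amp <- amplitudes_for_taus(tt, y2, taus0)
    if (is.null(amp)) next
    start <- c(setNames(log(taus0), paste0("ltau", seq_len(k))),
               setNames(pmax(amp$a, 0), paste0("a", seq_len(k))), C = amp$C)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = list(t = tt, y = y2),
                        start = as.list(start), lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    taus <- exp(cf[paste0("ltau", seq_len(k))])
    if (any(!is.finite(taus)) || any(taus <= 0) || any(taus > 100 * hi)) next
    ssr <- sum(resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(k = k, a = sgn * unname(cf[paste0("a", seq_len(k))]),
                   tau = unname(taus), offset = sgn * unname(cf[["C"]]),
                   ssr = ssr)
    }
  }
  best
}

exp_sum_formula <- function(k) {
  terms <- paste0("a", seq_len(k), " * exp(-t / exp(ltau", seq_len(k), "))",
                  collapse = " + ")
  stats::as.formula(paste("y ~", terms, "+ C"))
}

# Linear least-squares amplitudes (and offset) for fixed time constants.
amplitudes_for_taus <- function(tt, yy, taus) {
  X <- cbind(vapply(taus, function(tau) exp(-tt / tau), numeric(length(tt))), 1)
  sol <- tryCatch(qr.solve(X, yy), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  list(a = sol[seq_along(taus)], C = sol[length(sol)])
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %s, %d component(s)%s, SSR %.4g over %d points\n",
              x$direction, nrow(x$components),
              if (x$no_decay) " (no decay)" else "", x$ssr, x$n_points))
  if (nrow(x$components)) print(x$components)
  cat(sprintf("  offset C = %.4g pA; weighted tau = %.4g ms\n",
              x$offset, if (nrow(x$components)) weighted_tau(x) else NA))
  invisible(x)
}

#' Amplitude-weighted time constant of a multi-exponential fit
#'
#' The multi-exponential time course is summarized as
#' `sum(a_n * tau_n) / sum(a_n)`, the convention used to report deactivation
#' of macroscopic GABA-evoked currents.
#'
#' @param fit an `exp_fit` from [fit_exponentials()], or a data frame with
#'   columns `a` and `tau`.
#' @return Weighted time constant in ms.
#' @export
#' @examples
#' weighted_tau(data.frame(a = c(2, 1), tau = c(10, 100))) # 40
weighted_tau <- function(fit) {
  comp <- if (inherits(fit, "exp_fit")) fit$components else as_tibble(fit)
  stopifnot(all(c("a", "tau") %in% names(comp)))
  if (nrow(comp) < 1L) {
    abort("fit has no exponential components", class = "gabrisk_bad_input")
  }
  if (abs(sum(comp$a)) < .Machine$double.eps * max(abs(comp$a), 1)) {
    abort("amplitudes sum to zero; weighted tau undefined",
          class = "gabrisk_bad_input")
  }
  sum(comp$a * comp$tau) / sum(comp$a)
}

#' Peak current density
#'
#' Peak agonist-evoked current normalized by membrane capacitance. Densities
#' are reported as positive magnitudes regardless of the recording sign
#' convention (inward currents are negative at a -20 mV hold).
#'
#' @param peak peak current, pA (either sign).
#' @param capacitance cell capacitance, pF; must be positive.
#' @return Current density, pA/pF (non-negative).
#' @export
#' @examples
#' current_density(1000, 10) # 100
current_density <- function(peak, capacitance) {
  if (any(!is.finite(capacitance)) || any(capacitance <= 0)) {
    abort("`capacitance` must be positive", class = "gabrisk_bad_input")
  }
  abs(peak) / capacitance
}

#' Zinc inhibition of the GABA-evoked peak
#'
#' Percent reduction of the control GABA peak by co-applied zinc:
#' `100 * (1 - peak_gaba_zinc / peak_gaba)`. Low values (~10%) are diagnostic
#' of ternary alpha-beta-gamma receptors; binary alpha-beta receptors show
#' much stronger block.
#'
#' @param peak_gaba control peak magnitude, pA; must be > 0.
#' @param peak_gaba_zinc peak magnitude with zinc, pA.
#' @return Inhibition in percent.
#' @export
#' @examples
#' zinc_inhibition(100, 64.4) # 35.6
zinc_inhibition <- function(peak_gaba, peak_gaba_zinc) {
  peak_gaba <- abs(peak_gaba)
  peak_gaba_zinc <- abs(peak_gaba_zinc)
  if (any(peak_gaba <= 0)) {
    abort("control peak must be > 0", class = "gabrisk_bad_input")
  }
  100 * (1 - peak_gaba_zinc / peak_gaba)
}

#' Gating impairment ratio
#'
#' `(activation tau_variant / tau_wt) / (deactivation tau_variant / tau_wt)`.
#' A ratio > 1 means activation slowed more than deactivation slowed (or
#' deactivation accelerated), i.e. reduced channel gating; a ratio <= 1 means
#' preserved or increased gating.
#'
#' @param act_tau_variant,act_tau_wt activation time constants, ms.
#' @param deact_tau_variant,deact_tau_wt weighted deactivation time
#'   constants, ms.
#' @return A one-row tibble of class `gating_impairment` with
#'   `activation_fold`, `deactivation_fold` and `ratio`.
#' @export
#' @examples
#' gating_impairment_ratio(1.574, 1.063, 51.31, 83.78)$ratio # ~2.42
gating_impairment_ratio <- function(act_tau_variant, act_tau_wt,
                                    deact_tau_variant, deact_tau_wt) {
  vals <- c(act_tau_variant, act_tau_wt, deact_tau_variant, deact_tau_wt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all time constants must be finite and > 0",
          class = "gabrisk_bad_input")
  }
  act_fold <- act_tau_variant / act_tau_wt
  deact_fold <- deact_tau_variant / deact_tau_wt
  out <- tibble(activation_fold = act_fold,
                deactivation_fold = deact_fold,
                ratio = act_fold / deact_fold)
  class(out) <- c("gating_impairment", class(out))
  out
}

# ---- trace feature extraction ------------------------------------------

#' Baseline and peak of a current trace
#'
#' The baseline is the mean of the pre-stimulus window; the peak is the
#' extremum (relative to baseline) of the 5-point running-median smoothed
#' trace. Smoothing can be disabled.
#'
#' @param trace a `current_trace`.
#' @param smooth apply 5-point median smoothing before locating the peak.
#' @param from only consider times >= `from` ms when locating the peak
#'   (defaults to the pulse start when the trace carries a protocol).
#' @return A list with `baseline`, `baseline_sd`, `peak` (signed, relative to
#'   baseline), `peak_magnitude` and `peak_time`.
#' @export
trace_peak <- function(trace, smooth = TRUE, from = NULL) {
  proto <- attr(trace, "protocol")
  t0 <- if (!is.null(proto)) proto$pulse_start else {
    min(trace$time_ms) + 0.1 * diff(range(trace$time_ms))
  }
  pre <- trace$current_pA[trace$time_ms < t0]
  if (!length(pre)) pre <- trace$current_pA[1]
  base <- mean(pre)
  base_sd <- if (length(pre) > 1) sd(pre) else 0
  y <- trace$current_pA
  if (smooth && length(y) >= 5) y <- stats::runmed(y, 5)
  if (is.null(from)) from <- t0
  idx <- which(trace$time_ms >= from)
  rel <- y[idx] - base
  i <- idx[which.max(abs(rel))]
  list(baseline = base, baseline_sd = base_sd,
       peak = y[i] - base, peak_magnitude = abs(y[i] - base),
       peak_time = trace$time_ms[i])
}

# Activation window: first threshold crossing after the pulse start up to
# the peak. Threshold = 3 x baseline SD, with a 1%-of-peak floor so the rule
# is defined for noiseless traces.
activation_segment <- function(trace, smooth = TRUE) {
  proto <- attr(trace, "protocol")
  if (is.null(proto)) abort("trace has no stimulus protocol", class = "gabrisk_bad_input")
  pk <- trace_peak(trace, smooth = smooth)
  thr <- max(3 * pk$baseline_sd, 0.01 * pk$peak_magnitude)
  after <- trace$time_ms >= proto$pulse_start & trace$time_ms <= pk$peak_time
  dev <- abs(trace$current_pA - pk$baseline)
  hit <- which(after & dev >= thr)
  if (!length(hit)) return(NULL)
  c(trace$time_ms[hit[1]], pk$peak_time)
}

# Deactivation window: from the post-removal peak to the end of the record.
deactivation_segment <- function(trace, smooth = TRUE) {
  proto <- attr(trace, "protocol")
  if (is.null(proto)) abort("trace has no stimulus protocol", class = "gabrisk_bad_input")
  t_off <- proto$pulse_start + proto$pulse_duration
  pk <- trace_peak(trace, smooth = smooth, from = proto$pulse_start)
  start <- max(pk$peak_time, t_off)
  c(start, max(trace$time_ms))
}

#' Fit activation and deactivation kinetics of a brief-pulse trace
#'
#' Convenience wrapper for the standard 10-ms pulse protocol: locates the
#' activation window (first crossing of 3 x baseline SD to the peak) and the
#' deactivation window (post-removal peak to the end of the record), fits
#' each with [fit_exponentials()], and reports the activation onset tau and
#' weighted deactivation tau. By convention the activation tau is the
#' weighted tau of the activation fit when it is multi-component
#' (`activation_tau = "weighted"`); `"mono"` instead constrains the
#' activation fit to a single component.
#'
#' @inheritParams fit_exponentials
#' @param activation_tau `"weighted"` or `"mono"`.
#' @return A list with `activation` and `deactivation` `exp_fit`s plus
#'   `activation_tau` and `deactivation_weighted_tau` (ms).
#' @export
fit_gating <- function(trace, max_components = 4, alpha_F = 0.05,
                       activation_tau = c("weighted", "mono")) {
  activation_tau <- match.arg(activation_tau)
  act_seg <- activation_segment(trace)
  if (is.null(act_seg)) {
    abort("no activation onset found (flat trace?)", class = "gabrisk_fit_failure")
  }
  act_k <- if (activation_tau == "mono") 1L else max_components
  act <- fit_exponentials(trace, act_seg, direction = "activation",
                          max_components = act_k, alpha_F = alpha_F)
  deact <- fit_exponentials(trace, deactivation_segment(trace),
                            direction = "deactivation",
                            max_components = max_components, alpha_F = alpha_F)
  list(activation = act,
       deactivation = deact,
       activation_tau = if (act$no_decay) NA_real_ else weighted_tau(act),
       deactivation_weighted_tau = if (deact$no_decay) NA_real_ else weighted_tau(deact))
}

#' Per-cell kinetic summary
#'
#' Combines a brief-pulse kinetics trace, a long-pulse peak trace and an
#' optional zinc co-application trace into the per-cell summary row used for
#' group comparisons: peak current, current density (pA/pF), activation
#' onset tau, weighted deactivation tau and zinc inhibition (%).
#'
#' @param trace_kinetics 10-ms pulse trace used for activation/deactivation.
#' @param trace_peak_long 4-s pulse trace used for the peak current.
#' @param trace_zinc optional 4-s pulse trace with zinc pre/co-application.
#' @inheritParams fit_gating
#' @return A one-row tibble.
#' @export
kinetic_summary <- function(trace_kinetics, trace_peak_long, trace_zinc = NULL,
                            max_components = 4, alpha_F = 0.05,
                            activation_tau = c("weighted", "mono")) {
  gf <- fit_gating(trace_kinetics, max_components, alpha_F, activation_tau)
  pk <- trace_peak(trace_peak_long)
  cap <- attr(trace_peak_long, "capacitance")
  zn <- if (!is.null(trace_zinc)) {
    zinc_inhibition(pk$peak_magnitude, trace_peak(trace_zinc)$peak_magnitude)
  } else NA_real_
  tibble(peak_current = pk$peak_magnitude,
         capacitance = cap,
         current_density = current_density(pk$peak_magnitude, cap),
         activation_tau = gf$activation_tau,
         deactivation_weighted_tau = gf$deactivation_weighted_tau,
         zinc_inhibition = zn)
}
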