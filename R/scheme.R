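#' Five-state kinetic scheme for a GABA-A receptor channel
#'
#' Builds the Markov scheme used by [simulate_current()]: an unbound closed
#' state (C), two sequential GABA-binding steps (CA, CA2), a bi-liganded open
#' state (O) and a desensitized state (D),
#'
#' ```
#'   C  <-2*kon*c / koff->  CA  <-kon*c / 2*koff->  CA2
#'   CA2  <-beta_open / alpha_close->  O
#'   CA2  <-d_des / r_res->  D
#' ```
#'
#' Macroscopic current is `n_channels * P_open(t) * unitary_conductance *
#' (holding_potential - reversal_potential) / 1000` (pA, inward currents
#' negative at a -20 mV hold with chloride reversal near 0 mV).
#'
#' The default rate constants are illustrative: no kinetic parameters are
#' available for any specific receptor isoform, so the defaults were chosen
#' once to give wild-type-like macroscopic behaviour (sub-millisecond to
#' millisecond activation at 1 mM GABA, a weighted deactivation time constant
#' near 80 ms, mild desensitization during short pulses, and roughly 10%
#' inhibition of the peak by 10 uM zinc). They are a test-bed for the fitting
#' and classification machinery, not estimates for any real receptor.
#'
#' @param kon GABA binding rate constant, per molar per ms.
#' @param koff GABA unbinding rate constant, per ms.
#' @param beta_open channel opening rate from the bi-liganded closed state, per ms.
#' @param alpha_close channel closing rate, per ms.
#' @param d_des desensitization rate from the bi-liganded closed state, per ms.
#' @param r_res resensitization (recovery) rate, per ms.
#' @param n_channels number of channels in the cell.
#' @param unitary_conductance single-channel conductance, pS.
#' @param reversal_potential chloride reversal potential, mV.
#' @param holding_potential command potential, mV.
#' @param zinc_ic50 apparent IC50 for open-channel block by zinc, molar.
#'   Inhibition is modelled as scaling the open-channel current by
#'   `1 / (1 + [Zn] / zinc_ic50)`.
#' @param capacitance cell membrane capacitance, pF (carried onto traces).
#' @return An object of class `kinetic_scheme` (a named list of parameters).
#' @seealso [make_variant_scheme()], [simulate_current()]
#' @export
#' @examples
#' wt <- kinetic_scheme()
#' wt$beta_open / (wt$alpha_close + wt$beta_open) # saturating open probability
kinetic_scheme <- function(kon = 5e3,
                           koff = 0.02,
                           beta_open = 1.5,
                           alpha_close = 0.6,
                           d_des = 0.05,
                           r_res = 0.005,
                           n_channels = 20000,
                           unitary_conductance = 27,
                           reversal_potential = 0,
                           holding_potential = -20,
                           zinc_ic50 = 9e-5,
                           capacitance = 9) {
  rates <- c(kon = kon, koff = koff, beta_open = beta_open,
             alpha_close = alpha_close, d_des = d_des, r_res = r_res)
  if (any(!is.finite(rates))) {
    abort("all rate constants must be finite", class = "gabrisk_bad_scheme")
  }
  if (any(rates < 0)) {
    abort("all rate constants must be >= 0", class = "gabrisk_bad_scheme")
  }
  if (!is.finite(n_channels) || n_channels <= 0) {
    abort("`n_channels` must be a positive count", class = "gabrisk_bad_scheme")
  }
  if (!is.finite(capacitance) || capacitance <= 0) {
    abort("`capacitance` must be positive (pF)", class = "gabrisk_bad_scheme")
  }
  structure(
    list(states = c("C", "CA", "CA2", "O", "D"),
         kon = kon, koff = koff, beta_open = beta_open,
         alpha_close = alpha_close, d_des = d_des, r_res = r_res,
         n_channels = n_channels,
         unitary_conductance = unitary_conductance,
         reversal_potential = reversal_potential,
         holding_potential = holding_potential,
         zinc_ic50 = zinc_ic50,
         capacitance = capacitance),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> C - CA - CA2 - (O, D)\n")
  cat(sprintf("  kon %.3g /M/ms, koff %.3g /ms, beta %.3g /ms, alpha %.3g /ms, des %.3g /ms, res %.3g /ms\n",
              x$kon, x$koff, x$beta_open, x$alpha_close, x$d_des, x$r_res))
  cat(sprintf("  %d channels x %.3g pS, Vh %.3g mV, Erev %.3g mV, Cm %.3g pF\n",
              x$n_channels, x$unitary_conductance, x$holding_potential,
              x$reversal_potential, x$capacitance))
  invisible(x)
}

#' Stimulus protocol for an agonist application
#'
#' Describes a single rapid-exchange agonist application: a GABA concentration
#' step of `pulse_duration` ms starting at `pulse_start` ms, with optional
#' zinc pre-application. The solution exchange is modelled as an exponential
#' concentration relaxation with time constant `exchange_time` (the default
#' 0.4 ms sits within typical 200-400 us tip-exchange times of fast perfusion
#' systems). Sampling defaults to 10 kHz, the usual digitization rate for
#' whole-cell recordings of this kind.
#'
#' @param gaba_concentration GABA concentration during the pulse, molar.
#' @param pulse_start pulse onset, ms.
#' @param pulse_duration pulse length, ms (10 ms for kinetics protocols,
#'   4000 ms for peak/concentration-response protocols).
#' @param record_duration total length of the recording, ms. Defaults to the
#'   pulse plus a tail long enough to capture deactivation.
#' @param zinc_concentration co-applied zinc concentration, molar (0 = none).
#' @param zinc_preapplication zinc pre-application time before the GABA pulse,
#'   ms (10 000 ms in the standard protocol when zinc is used).
#' @param exchange_time solution exchange time constant, ms.
#' @param sample_rate_khz sampling rate, kHz.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(gaba_concentration = 1e-3,
                              pulse_start = 10,
                              pulse_duration = 10,
                              record_duration = NULL,
                              zinc_concentration = 0,
                              zinc_preapplication = if (zinc_concentration > 0) 1e4 else 0,
                              exchange_time = 0.4,
                              sample_rate_khz = 10) {
  if (pulse_duration <= 0 || pulse_start < 0) {
    abort("pulse timings must be positive", class = "gabrisk_bad_protocol")
  }
  if (exchange_time <= 0 || exchange_time >= pulse_duration) {
    abort("`exchange_time` must be positive and shorter than the pulse",
          class = "gabrisk_bad_protocol")
  }
  if (is.null(record_duration)) {
    tail_ms <- if (pulse_duration <= 100) 600 else 1000
    record_duration <- pulse_start + pulse_duration + tail_ms
  }
  if (record_duration <= pulse_start + pulse_duration) {
    abort("`record_duration` must extend beyond the pulse",
          class = "gabrisk_bad_protocol")
  }
  structure(
    list(gaba_concentration = gaba_concentration,
         pulse_start = pulse_start,
         pulse_duration = pulse_duration,
         record_duration = record_duration,
         zinc_concentration = zinc_concentration,
         zinc_preapplication = zinc_preapplication,
         exchange_time = exchange_time,
         sample_rate_khz = sample_rate_khz),
    class = "stimulus_protocol"
  )
}

#' Derive a variant scheme by scaling wild-type rate constants
#'
#' Applies named multiplicative perturbations to the rate constants of a
#' wild-type scheme, e.g. `c(beta_open = 0.3)` to slow channel opening or
#' `c(koff = 3)` to speed agonist unbinding (the combination that produces a
#' gating-impaired phenotype: slowed activation and accelerated deactivation).
#'
#' @param wild_type a [kinetic_scheme()].
#' @param perturbation named numeric vector of positive multipliers; names
#'   must be rate constants of the scheme (`kon`, `koff`, `beta_open`,
#'   `alpha_close`, `d_des`, `r_res`).
#' @return A new `kinetic_scheme`; the wild type is unchanged.
#' @export
#' @examples
#' wt <- kinetic_scheme()
#' slow <- make_variant_scheme(wt, c(beta_open = 0.3, koff = 3))
make_variant_scheme <- function(wild_type, perturbation = numeric()) {
  stopifnot(inherits(wild_type, "kinetic_scheme"))
  rate_names <- c("kon", "koff", "beta_open", "alpha_close", "d_des", "r_res")
  if (length(perturbation)) {
    bad <- setdiff(names(perturbation), rate_names)
    if (is.null(names(perturbation)) || any(names(perturbation) == "") || length(bad)) {
      abort(paste0("unknown rate name(s): ",
                   paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
            class = "gabrisk_bad_perturbation")
    }
    if (any(!is.finite(perturbation)) || any(perturbation <= 0)) {
      abort("multipliers must be finite and > 0", class = "gabrisk_bad_perturbation")
    }
  }
  variant <- wild_type
  for (nm in names(perturbation)) {
    variant[[nm]] <- variant[[nm]] * unname(perturbation[[nm]])
  }
  variant
}
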