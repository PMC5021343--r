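#' Construct a current trace
#'
#' A `current_trace` is a tibble with columns `time_ms` (uniform, strictly
#' increasing) and `current_pA`, carrying the cell capacitance, the stimulus
#' protocol and the simulation seed as attributes. [simulate_current()]
#' produces them; this constructor lets synthetic or imported recordings
#' enter the same pipeline.
#'
#' @param time_ms time grid in ms, uniform and strictly increasing.
#' @param current_pA current samples in pA, same length as `time_ms`.
#' @param capacitance cell capacitance, pF.
#' @param protocol optional [stimulus_protocol()].
#' @param seed optional integer seed recorded for provenance.
#' @return A tibble of class `current_trace`.
#' @export
new_current_trace <- function(time_ms, current_pA, capacitance = NA_real_,
                              protocol = NULL, seed = NA_integer_) {
  if (length(time_ms) != length(current_pA)) {
    abort("`time_ms` and `current_pA` must have the same length",
          class = "gabrisk_bad_trace")
  }
  if (length(time_ms) < 2L) {
    abort("a trace needs at least two samples", class = "gabrisk_bad_trace")
  }
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("`time_ms` must be strictly increasing on a uniform grid",
          class = "gabrisk_bad_trace")
  }
  if (any(!is.finite(current_pA))) {
    abort("`current_pA` must be finite", class = "gabrisk_bad_trace")
  }
  out <- tibble(time_ms = as.numeric(time_ms), current_pA = as.numeric(current_pA))
  class(out) <- c("current_trace", class(out))
  attr(out, "capacitance") <- capacitance
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

# GABA concentration profile: exponential relaxation toward the commanded
# step with the protocol's exchange time constant.
gaba_profile <- function(t, protocol) {
  c0 <- protocol$gaba_concentration
  t0 <- protocol$pulse_start
  t1 <- protocol$pulse_start + protocol$pulse_duration
  tau <- protocol$exchange_time
  conc <- numeric(length(t))
  during <- t >= t0 & t < t1
  after <- t >= t1
  conc[during] <- c0 * (1 - exp(-(t[during] - t0) / tau))
  c_end <- c0 * (1 - exp(-(t1 - t0) / tau))
  conc[after] <- c_end * exp(-(t[after] - t1) / tau)
  conc
}

scheme_derivs <- function(t, state, parms) {
  conc <- gaba_profile(t, parms$protocol)
  with(as.list(state), {
    b1 <- 2 * parms$kon * conc # C -> CA
    b2 <- parms$kon * conc     # CA -> CA2
    dC <- parms$koff * CA - b1 * C
    dCA <- b1 * C + 2 * parms$koff * CA2 - (parms$koff + b2) * CA
    dCA2 <- b2 * CA + parms$alpha_close * O + parms$r_res * D -
      (2 * parms$koff + parms$beta_open + parms$d_des) * CA2
    dO <- parms$beta_open * CA2 - parms$alpha_close * O
    dD <- parms$d_des * CA2 - parms$r_res * D
    list(c(dC, dCA, dCA2, dO, dD))
  })
}

#' Simulate a macroscopic GABA-evoked current
#'
#' Integrates the five-state scheme's occupancy under a stimulus protocol
#' (stiff-capable adaptive integration, relative tolerance 1e-8) and converts
#' open probability to whole-cell current
#' `I(t) = n_channels * P_open(t) * g * (V_hold - E_rev) / 1000` pA, with
#' additive i.i.d. Gaussian noise. When the protocol includes zinc, the
#' open-channel current is scaled by `1 / (1 + [Zn] / zinc_ic50)`
#' (pre-application is assumed long enough for the block to equilibrate).
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [stimulus_protocol()].
#' @param noise_sd standard deviation of the additive recording noise, pA.
#' @param seed integer seed; the trace is bit-identical for a fixed seed.
#' @param keep_occupancy if `TRUE`, attach the full state-occupancy matrix as
#'   attribute `"occupancy"` (used to audit probability conservation).
#' @return A [new_current_trace()] tibble.
#' @export
#' @examples
#' tr <- simulate_current(kinetic_scheme(), stimulus_protocol(), noise_sd = 2, seed = 1)
#' range(tr$current_pA)
simulate_current <- function(scheme, protocol, noise_sd = 0, seed = 1L,
                             keep_occupancy = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be finite and >= 0", class = "gabrisk_bad_input")
  }
  dt <- 1 / protocol$sample_rate_khz
  times <- seq(0, protocol$record_duration, by = dt)
  y0 <- c(C = 1, CA = 0, CA2 = 0, O = 0, D = 0)
  parms <- c(scheme[c("kon", "koff", "beta_open", "alpha_close", "d_des", "r_res")],
             list(protocol = protocol))
  sol <- deSolve::lsoda(y0, times, scheme_derivs, parms,
                        rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times)) {
    info <- utils::capture.output(deSolve::diagnostics(sol))
    abort(paste0("ODE solver failed to integrate the scheme (istate = ",
                 attr(sol, "istate")[1L], ")"),
          class = "gabrisk_solver_failure", body = info)
  }
  occ <- sol[, c("C", "CA", "CA2", "O", "D"), drop = FALSE]
  p_open <- occ[, "O"]
  drive <- scheme$holding_potential - scheme$reversal_potential
  block <- if (protocol$zinc_concentration > 0) {
    1 / (1 + protocol$zinc_concentration / scheme$zinc_ic50)
  } else 1
  current <- scheme$n_channels * p_open * scheme$unitary_conductance *
    drive / 1000 * block
  if (noise_sd > 0) {
    current <- withr_seed(seed, current + rnorm(length(current), sd = noise_sd))
  }
  out <- new_current_trace(times, current, capacitance = scheme$capacitance,
                           protocol = protocol, seed = seed)
  if (keep_occupancy) attr(out, "occupancy") <- occ
  out
}

# Evaluate an expression under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
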