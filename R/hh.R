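#' Canonical Hodgkin-Huxley parameter set
#'
#' The 1952 squid-axon parameterization in the modern voltage convention
#' (resting potential near -65 mV). Units: capacitance uF/cm^2, conductances
#' mS/cm^2, voltages mV, currents uA/cm^2, time ms internally.
#'
#' @param C_m Membrane capacitance (uF/cm^2).
#' @param g_Na,g_K,g_L Maximal conductances (mS/cm^2).
#' @param E_Na,E_K,E_L Reversal potentials (mV).
#' @return An object of class `"hh_params"`.
#' @export
hh_params <- function(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                      E_Na = 50, E_K = -77, E_L = -54.387) {
  stopifnot(C_m > 0, g_Na > 0, g_K > 0, g_L > 0)
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L),
            class = "hh_params")
}

## Standard alpha/beta gating rates (V in mV, rates in 1/ms), with the usual
## removable singularities handled explicitly.
hh_rates <- function(V) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  list(
    am = 0.1 * vtrap(-(V + 40), 10),
    bm = 4 * exp(-(V + 65) / 18),
    ah = 0.07 * exp(-(V + 65) / 20),
    bh = 1 / (1 + exp(-(V + 35) / 10)),
    an = 0.01 * vtrap(-(V + 55), 10),
    bn = 0.125 * exp(-(V + 65) / 80)
  )
}

#' Steady-state HH gating variables
#'
#' Closed-form `alpha/(alpha+beta)` values of m, h, n at a membrane voltage.
#'
#' @param V Membrane voltage (mV).
#' @return Named numeric vector `c(m, h, n)`.
#' @export
hh_gating_inf <- function(V) {
  r <- hh_rates(V)
  c(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn))
}

#' Simulate the Hodgkin-Huxley reference neuron
#'
#' Integrates the canonical four-ODE squid-axon model. The stimulus program
#' is interpreted in uA/cm^2 (numerically: amperes in the program are read as
#' uA/cm^2, so `2e-6` in a shared protocol template means 2 uA there and
#' 2 uA/cm^2 here when `current_scale = 1e6`). The returned trace uses the
#' same container as [simulate_neuron()] with `V_mem` in volts, so the whole
#' spike-analysis layer applies unchanged.
#'
#' @param p An [hh_params()] object.
#' @param stim A [stimulus_program()]; amplitudes multiplied by
#'   `current_scale` give uA/cm^2.
#' @param t_span Simulation length (s).
#' @param dt_out Output sampling (s).
#' @param current_scale Conversion from program amperes to uA/cm^2.
#' @param rtol,atol Solver tolerances.
#' @return A `coecn_trace` object; `I_Na`, `I_K` are in A/cm^2 equivalents
#'   (uA/cm^2 * 1e-6) and `V_mem` in volts.
#' @export
hh_simulate <- function(p, stim = NULL, t_span = 0.5, dt_out = 1e-5,
                        current_scale = 1e6, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "hh_params"), t_span > 0)
  ## rest: V = -65 mV, gates at steady state
  V0 <- -65
  g0 <- hh_gating_inf(V0)
  init <- c(V = V0, m = g0[["m"]], h = g0[["h"]], n = g0[["n"]])
  times_ms <- seq(0, t_span * 1000, by = dt_out * 1000)
  func <- function(t_ms, y, parms) {
    V <- y[1L]; m <- y[2L]; h <- y[3L]; n <- y[4L]
    r <- hh_rates(V)
    I_Na <- p$g_Na * m^3 * h * (V - p$E_Na)
    I_K <- p$g_K * n^4 * (V - p$E_K)
    I_L <- p$g_L * (V - p$E_L)
    I_in <- if (is.null(stim)) 0
            else evaluate_stimulus(stim, t_ms / 1000) * current_scale
    list(c((I_in - I_Na - I_K - I_L) / p$C_m,
           r$am * (1 - m) - r$bm * m,
           r$ah * (1 - h) - r$bh * h,
           r$an * (1 - n) - r$bn * n))
  }
  sol <- deSolve::lsoda(init, times_ms, func, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  V <- sol[, "V"]; m <- sol[, "m"]; h <- sol[, "h"]; n <- sol[, "n"]
  I_Na <- p$g_Na * m^3 * h * (V - p$E_Na) * 1e-6
  I_K <- p$g_K * n^4 * (V - p$E_K) * 1e-6
  tt <- sol[, 1] / 1000
  I_in <- if (is.null(stim)) rep(0, length(tt)) else evaluate_stimulus(stim, tt)
  structure(list(t = unname(tt), V_mem = unname(V) / 1000,
                 V_gk = unname(sol[, "n"]),  # recovery variable slot
                 I_in = I_in, I_Na = unname(I_Na), I_K = unname(I_K),
                 I_leak = unname(p$g_L * (V - p$E_L) * 1e-6),
                 gates = list(m = unname(m), h = unname(h), n = unname(n)),
                 meta = list(config_digest = config_digest(p),
                             method = "lsoda", rtol = rtol, atol = atol,
                             dt_out = dt_out, seed = NA_integer_)),
            class = "coecn_trace")
}
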