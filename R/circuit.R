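#' Circuit parameters for the c-OECN
#'
#' Assembles the full two-node spiking circuit: the membrane node (charged by
#' the input current and the antiambipolar Na-OECT, discharged by the K-OECT
#' and a small leak) and the delayed K-OECT gate node (a first-order lag of
#' the membrane voltage through `R_dk` into `C_gK`). The sodium branch sits
#' between the supply `E_Na` and the membrane node, so its effective drain
#' bias is `E_Na - V_mem`; the potassium branch sits between the membrane
#' node and `E_K`, so its effective drain bias is `V_mem - E_K`. An inverting
#' amplifier maps `V_mem` to the Na-OECT gate.
#'
#' All units SI: volts, amperes, farads, ohms, siemens, seconds.
#'
#' @param E_Na Sodium supply voltage (V), `> 0` (default 0.5).
#' @param E_K Potassium supply voltage (V), typically in \[-0.072, -0.012\].
#' @param C_mem External membrane capacitance (F); may be 0 to rely on the
#'   intrinsic capacitance only.
#' @param C_int Intrinsic membrane-node capacitance (F), always in parallel
#'   with `C_mem`.
#' @param R_dk Delay resistance into the K-OECT gate (Ohm).
#' @param C_gK K-OECT gate capacitance (F); `R_dk * C_gK` is the potassium
#'   activation delay.
#' @param G_L Leak conductance (S) to `E_L`.
#' @param E_L Leak reversal voltage (V).
#' @param amplifier An [amplifier_params()] object.
#' @param na_params An [antiambipolar_params()] object (sodium branch).
#' @param k_params An [oect_params()] object (potassium branch).
#' @param na_electrolyte Optional [electrolyte()] routed to the Na-OECT.
#' @param k_electrolyte Optional [electrolyte()] routed to the K-OECT.
#' @param C_g_Na Na-OECT gate capacitance (F), used only in the power
#'   bookkeeping (amplifier output-stage current = gate charging current).
#' @return An object of class `"coecn_config"`.
#' @export
circuit_params <- function(E_Na = 0.5, E_K = -0.05,
                           C_mem = 1e-6, C_int = 1e-8,
                           R_dk = 4.7e5, C_gK = 6e-8,
                           G_L = 2e-5, E_L = 0.16,
                           amplifier = amplifier_params(),
                           na_params = antiambipolar_params(),
                           k_params = oect_params(),
                           na_electrolyte = NULL,
                           k_electrolyte = NULL,
                           C_g_Na = 1e-7) {
  stopifnot(C_mem + C_int > 0, R_dk > 0, C_gK > 0, E_Na > 0, G_L >= 0,
            C_g_Na >= 0,
            inherits(amplifier, "amp_params"),
            inherits(na_params, "aap_params"),
            inherits(k_params, "oect_params"))
  if (!is.null(na_electrolyte))
    stopifnot(inherits(na_electrolyte, "electrolyte"),
              na_electrolyte$target == "Na_OECT")
  if (!is.null(k_electrolyte))
    stopifnot(inherits(k_electrolyte, "electrolyte"),
              k_electrolyte$target == "K_OECT")
  structure(list(E_Na = E_Na, E_K = E_K, C_mem = C_mem, C_int = C_int,
                 R_dk = R_dk, C_gK = C_gK, G_L = G_L, E_L = E_L,
                 amplifier = amplifier, na_params = na_params,
                 k_params = k_params,
                 na_electrolyte = na_electrolyte,
                 k_electrolyte = k_electrolyte,
                 C_g_Na = C_g_Na),
            class = "coecn_config")
}

#' @export
print.coecn_config <- function(x, ...) {
  cat("c-OECN circuit configuration\n")
  cat(sprintf("  E_Na = %.3g V, E_K = %.3g V\n", x$E_Na, x$E_K))
  cat(sprintf("  C_mem = %.3g F (+ C_int = %.3g F), R_dk = %.3g Ohm, C_gK = %.3g F\n",
              x$C_mem, x$C_int, x$R_dk, x$C_gK))
  cat(sprintf("  leak: G_L = %.3g S to E_L = %.3g V\n", x$G_L, x$E_L))
  print(x$amplifier)
  print(x$na_params)
  print(x$k_params)
  if (!is.null(x$na_electrolyte)) print(x$na_electrolyte)
  if (!is.null(x$k_electrolyte)) print(x$k_electrolyte)
  invisible(x)
}

## Electrolyte-modulated device parameters, resolved once per run.
effective_devices <- function(p) {
  list(na = modulated_na_params(p$na_params, p$na_electrolyte),
       k = modulated_k_params(p$k_params, p$k_electrolyte))
}

## Device currents as pure functions of the node voltages. Vectorized over
## states so traces can be post-processed in one call.
circuit_currents <- function(V_mem, V_gk, p, dev = effective_devices(p)) {
  V_g_na <- amplifier_output(V_mem, p$amplifier)
  I_Na <- antiambipolar_current(V_g_na, pmax(p$E_Na - V_mem, 0), dev$na)
  I_K <- oect_current(V_gk - p$E_K, pmax(V_mem - p$E_K, 0), dev$k)
  I_leak <- p$G_L * (V_mem - p$E_L)
  list(I_Na = I_Na, I_K = I_K, I_leak = I_leak, V_g_na = V_g_na)
}

#' Right-hand side of the c-OECN ODE system
#'
#' Kirchhoff's current law at the membrane node and the first-order lag at
#' the K-OECT gate node:
#' \deqn{(C_{mem}+C_{int})\,\dot V_{mem} = I_{in}(t) + I_{Na} - I_K - G_L (V_{mem}-E_L)}
#' \deqn{\dot V_{gk} = (V_{mem} - V_{gk}) / (R_{dk} C_{gK})}
#' with \eqn{I_{Na}} the antiambipolar current at gate voltage
#' `amplifier_output(V_mem)` and drain bias `max(E_Na - V_mem, 0)`, and
#' \eqn{I_K} the standard OECT current at gate-source voltage `V_gk - E_K`
#' and drain bias `max(V_mem - E_K, 0)`. A pure function of `(state, t)`.
#'
#' @param state Named numeric vector or list with `V_mem` and `V_gk` (V).
#' @param t Time (s).
#' @param p A [circuit_params()] object.
#' @param stim A [stimulus_program()] (or `NULL` for zero input).
#' @param dev Pre-resolved effective device parameters (internal use).
#' @return List with `dV_mem`, `dV_gk` (V/s) and the currents `I_in`,
#'   `I_Na`, `I_K`, `I_leak` (A).
#' @export
circuit_rhs <- function(state, t, p, stim = NULL,
                        dev = effective_devices(p)) {
  V_mem <- state[["V_mem"]]
  V_gk <- state[["V_gk"]]
  if (!is.finite(V_mem)) stop("non-finite state at node V_mem")
  if (!is.finite(V_gk)) stop("non-finite state at node V_gk")
  I_in <- if (is.null(stim)) 0 else evaluate_stimulus(stim, t)
  cc <- circuit_currents(V_mem, V_gk, p, dev)
  dV_mem <- (I_in + cc$I_Na - cc$I_K - cc$I_leak) / (p$C_mem + p$C_int)
  dV_gk <- (V_mem - V_gk) / (p$R_dk * p$C_gK)
  list(dV_mem = dV_mem, dV_gk = dV_gk, I_in = I_in, I_Na = cc$I_Na,
       I_K = cc$I_K, I_leak = cc$I_leak)
}

## Scalar stimulus evaluator optimized for solver right-hand sides: the
## noise path interpolator is built once (approxfun), segments are unrolled
## to plain vectors. Semantically identical to evaluate_stimulus().
make_fast_stimulus <- function(stim) {
  if (is.null(stim)) return(function(t) 0)
  base <- stim$baseline
  ns <- length(stim$segments)
  t0 <- vapply(stim$segments, `[[`, 0, "t_start")
  t1 <- t0 + vapply(stim$segments, `[[`, 0, "duration")
  is_ramp <- vapply(stim$segments, function(s) s$kind == "ramp", TRUE)
  a0 <- vapply(stim$segments, function(s)
    if (s$kind == "ramp") s$start else s$amplitude, 0)
  a1 <- vapply(stim$segments, function(s)
    if (s$kind == "ramp") s$end else s$amplitude, 0)
  nf <- if (!is.null(stim$noise_path) && stim$noise$sigma > 0)
    stats::approxfun(stim$noise_path$t, stim$noise_path$x, rule = 2)
  else NULL
  function(t) {
    out <- base
    if (ns) for (i in seq_len(ns)) {
      if (t >= t0[i] && t < t1[i]) {
        out <- out + if (is_ramp[i])
          a0[i] + (a1[i] - a0[i]) * (t - t0[i]) / (t1[i] - t0[i])
        else a0[i]
        break
      }
    }
    if (!is.null(nf)) out <- out + nf(t)
    out
  }
}

## Solver right-hand side with device laws inlined on plain scalars (the
## exported circuit_rhs() is the reference implementation; tests assert the
## two agree along trajectories).
make_circuit_rhs <- function(p, dev, stim) {
  fstim <- make_fast_stimulus(stim)
  E_Na <- p$E_Na; E_K <- p$E_K; C <- p$C_mem + p$C_int
  G_L <- p$G_L; E_L <- p$E_L; tau_gk <- p$R_dk * p$C_gK
  gain <- p$amplifier$gain; off <- p$amplifier$offset
  rlo <- p$amplifier$rail_low; rhi <- p$amplifier$rail_high
  na <- dev$na
  ipk0 <- na$I_peak0; kpk <- na$k_peak; vp0 <- na$V_P0; kvp <- na$k_VP
  sr <- na$sigma_rise; sf <- na$sigma_fall; ksg <- na$k_sigma
  vref <- na$V_DS_ref
  kg <- dev$k$K_g; vt <- dev$k$V_T
  function(t, y, parms) {
    V <- y[1L]; W <- y[2L]
    vg <- gain * V + off
    if (vg < rlo) vg <- rlo else if (vg > rhi) vg <- rhi
    vds <- E_Na - V
    if (vds < 0) vds <- 0
    dv <- vds - vref
    ipk <- ipk0 + kpk * dv
    if (ipk < 0) ipk <- 0
    vp <- vp0 + kvp * dv
    sig <- (if (vg < vp) sr else sf) * (1 + ksg * dv)
    ina <- ipk * exp(-(vg - vp)^2 / (2 * sig * sig))
    vov <- W - E_K - vt
    ik <- if (vov > 0) {
      veff <- V - E_K
      if (veff > vov) veff <- vov
      if (veff < 0) veff <- 0
      kg * (vov * veff - veff * veff / 2)
    } else 0
    list(c((fstim(t) + ina - ik - G_L * (V - E_L)) / C, (V - W) / tau_gk))
  }
}

## Digest of a configuration for trace metadata / manifests: md5 of the
## canonical serialization.
config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Simulate the c-OECN circuit
#'
#' Integrates the two-node ODE system with an adaptive implicit-capable
#' solver (`deSolve::lsoda`, the default — the Gaussian nonlinearity plus the
#' millisecond-scale gate lag make the system moderately stiff) or with
#' fixed-step RK4 for bit-reproducible regression runs. Device currents in
#' the returned trace are recomputed from the state trajectory, so they
#' satisfy the same current laws as the integrator saw.
#'
#' @param p A [circuit_params()] object.
#' @param stim A [stimulus_program()] (or `NULL` for zero input).
#' @param t_span Simulation length (s), `> 0`.
#' @param dt_out Output sampling interval (s); default 1e-4 (refine for
#'   high-frequency configurations).
#' @param method `"lsoda"` (adaptive) or `"rk4"` (fixed step `dt_out`).
#' @param rtol,atol Solver tolerances (lsoda).
#' @param hmax Maximum solver step (s); default caps at 1 ms so short
#'   stimulus segments and noise structure are never stepped over.
#' @param init Initial [CircuitState]: named vector `c(V_mem=, V_gk=)`;
#'   default is the resting state of `p`.
#' @return An object of class `"coecn_trace"`: a list with vectors `t`,
#'   `V_mem`, `V_gk`, `I_in`, `I_Na`, `I_K`, `I_leak` and a `meta` list
#'   (config digest, solver settings, noise seed).
#' @export
simulate_neuron <- function(p, stim = NULL, t_span = 5, dt_out = 1e-4,
                            method = c("lsoda", "rk4"),
                            rtol = 1e-8, atol = 1e-10, hmax = NULL,
                            init = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(p, "coecn_config"), t_span > 0, dt_out > 0,
            rtol > 0, atol > 0)
  dev <- effective_devices(p)
  if (is.null(init)) {
    rs <- resting_state(p)
    init <- c(V_mem = rs$V_mem, V_gk = rs$V_gk)
  } else {
    init <- c(V_mem = unname(init[["V_mem"]]), V_gk = unname(init[["V_gk"]]))
  }
  if (is.null(hmax)) {
    hmax <- 1e-3
    if (!is.null(stim) && length(stim$segments))
      hmax <- min(hmax, min(vapply(stim$segments, `[[`, 0, "duration")) / 4)
  }
  times <- seq(0, t_span, by = dt_out)
  func <- make_circuit_rhs(p, dev, stim)
  sol <- if (method == "lsoda") {
    deSolve::lsoda(init, times, func, parms = NULL, rtol = rtol,
                   atol = atol, hmax = hmax, maxsteps = 50000)
  } else {
    deSolve::rk4(init, times, func, parms = NULL)
  }
  if (nrow(sol) < length(times))
    stop("solver failed at t = ", sol[nrow(sol), 1],
         " s (step collapse); last valid state returned in the error")
  V_mem <- sol[, "V_mem"]; V_gk <- sol[, "V_gk"]
  if (any(abs(V_mem) > 1))
    warning("V_mem left the [-1, 1] V sanity band; check parameters")
  cc <- circuit_currents(V_mem, V_gk, p, dev)
  I_in <- if (is.null(stim)) rep(0, length(times))
          else evaluate_stimulus(stim, sol[, "time"])
  structure(list(t = unname(sol[, "time"]), V_mem = unname(V_mem),
                 V_gk = unname(V_gk), I_in = I_in,
                 I_Na = cc$I_Na, I_K = cc$I_K, I_leak = cc$I_leak,
                 meta = list(config_digest = config_digest(p),
                             method = method, rtol = rtol, atol = atol,
                             hmax = hmax, dt_out = dt_out,
                             seed = if (!is.null(stim) && !is.null(stim$noise))
                               stim$noise$seed else NA_integer_)),
            class = "coecn_trace")
}

#' @export
print.coecn_trace <- function(x, ...) {
  cat(sprintf("c-OECN trace: %d samples over %.4g s (dt = %.3g s, %s)\n",
              length(x$t), max(x$t), x$meta$dt_out, x$meta$method))
  cat(sprintf("  V_mem range [%.4g, %.4g] V; max |I_Na| = %.3g A, max |I_K| = %.3g A\n",
              min(x$V_mem), max(x$V_mem), max(abs(x$I_Na)), max(abs(x$I_K))))
  invisible(x)
}

#' @export
summary.coecn_trace <- function(object, threshold = 0.25, ...) {
  st <- detect_spikes(object, threshold = threshold)
  n <- length(st$spike_times)
  rate <- if (n >= 2) 1 / mean(diff(st$spike_times)) else 0
  out <- list(n_samples = length(object$t), t_span = max(object$t),
              V_rest_like = stats::median(object$V_mem),
              V_peak = max(object$V_mem), V_min = min(object$V_mem),
              n_spikes = n, rate_Hz = rate)
  class(out) <- "summary.coecn_trace"
  out
}

#' @export
print.summary.coecn_trace <- function(x, ...) {
  cat(sprintf("c-OECN trace summary: %d samples, %.4g s\n",
              x$n_samples, x$t_span))
  cat(sprintf("  V_mem: median %.4g V, max %.4g V, min %.4g V\n",
              x$V_rest_like, x$V_peak, x$V_min))
  cat(sprintf("  spikes: %d (steady rate %.3g Hz)\n", x$n_spikes, x$rate_Hz))
  invisible(x)
}

#' @export
as.data.frame.coecn_trace <- function(x, ...) {
  data.frame(t_s = x$t, V_mem_V = x$V_mem, V_gk_V = x$V_gk,
             I_in_A = x$I_in, I_Na_A = x$I_Na, I_K_A = x$I_K)
}

#' @export
plot.coecn_trace <- function(x, which = c("V_mem", "currents"), ...) {
  which <- match.arg(which)
  if (which == "V_mem") {
    graphics::plot(x$t, x$V_mem, type = "l", xlab = "time (s)",
                   ylab = "V_mem (V)", ...)
  } else {
    graphics::plot(x$t, x$I_Na * 1e6, type = "l", xlab = "time (s)",
                   ylab = "current (uA)", col = "firebrick", ...)
    graphics::lines(x$t, x$I_K * 1e6, col = "steelblue")
    graphics::legend("topright", c("I_Na", "I_K"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}

#' Write / read a simulation trace as CSV
#'
#' Columns: `t_s`, `V_mem_V`, `V_gk_V`, `I_in_A`, `I_Na_A`, `I_K_A`.
#'
#' @param trace A `coecn_trace`.
#' @param path Output file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a data.frame.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) utils::read.csv(path)

#' Resting state of the circuit
#'
#' Finds the quiescent operating point (zero input current) as a root of the
#' circuit right-hand side, by damped Newton iteration started from the leak
#' reversal `E_L` (at rest the gate node equals the membrane node, so the
#' problem is one-dimensional). The returned state is verified stable: both
#' eigenvalues of the 2x2 Jacobian must have negative real part. If Newton
#' stalls, a bracketing grid search over the operating band is used.
#'
#' @param p A [circuit_params()] object.
#' @return A list with `V_mem`, `V_gk` (equal at rest) and the Jacobian
#'   eigenvalues in attribute `"eigenvalues"`.
#' @export
resting_state <- function(p) {
  stopifnot(inherits(p, "coecn_config"))
  dev <- effective_devices(p)
  g <- function(V) {
    cc <- circuit_currents(V, V, p, dev)
    cc$I_Na - cc$I_K - cc$I_leak
  }
  dg <- function(V, h = 1e-7) (g(V + h) - g(V - h)) / (2 * h)
  V <- p$E_L
  ok <- FALSE
  for (it in 1:100) {
    f <- g(V)
    if (abs(f) < 1e-15) { ok <- TRUE; break }
    d <- dg(V)
    if (!is.finite(d) || d == 0) break
    step <- -f / d
    ## damping: never move more than 50 mV per iteration
    step <- sign(step) * min(abs(step), 0.05)
    V <- V + step
    if (abs(step) < 1e-12) { ok <- TRUE; break }
  }
  if (!ok || !is_stable_root(V, p, dev)) {
    V <- stable_root_scan(g, p, dev)
    if (is.na(V))
      stop("no stable resting state found; review G_L/E_L and device parameters")
  }
  st <- list(V_mem = V, V_gk = V)
  attr(st, "eigenvalues") <- rest_jacobian_eigen(V, p, dev)
  st
}

rest_jacobian_eigen <- function(V, p, dev, h = 1e-7) {
  f <- function(vm, vg) {
    r <- circuit_rhs(list(V_mem = vm, V_gk = vg), 0, p, NULL, dev)
    c(r$dV_mem, r$dV_gk)
  }
  J <- cbind((f(V + h, V) - f(V - h, V)) / (2 * h),
             (f(V, V + h) - f(V, V - h)) / (2 * h))
  eigen(J, only.values = TRUE)$values
}

is_stable_root <- function(V, p, dev) {
  ev <- rest_jacobian_eigen(V, p, dev)
  all(Re(ev) < 0)
}

stable_root_scan <- function(g, p, dev) {
  grid <- seq(-0.2, p$E_Na, by = 1e-3)
  gv <- vapply(grid, g, 0.0)
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    if (is_stable_root(r, p, dev)) return(r)
  }
  NA_real_
}
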