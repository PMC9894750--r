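#' Detect spikes in a membrane-voltage trace
#'
#' Upward threshold crossings with linear interpolation between samples and a
#' minimum-separation (refractory) filter. Deterministic; a threshold outside
#' the trace range yields an empty spike train, not an error.
#'
#' @param trace A `coecn_trace` (from [simulate_neuron()] or
#'   [hh_simulate()]).
#' @param threshold Detection threshold (V). The default 0.25 V sits midway
#'   between the 175 mV resting level and the 0.34 V depolarization peak of
#'   the reference configuration.
#' @param refractory_min Minimum separation between detected spikes (s).
#' @return An object of class `"spike_train"`: list with `spike_times` (s),
#'   `threshold`, `refractory_min`.
#' @export
detect_spikes <- function(trace, threshold = 0.25, refractory_min = 0) {
  stopifnot(length(trace$t) > 0)
  v <- trace$V_mem
  t <- trace$t
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  times <- if (length(up)) {
    frac <- (threshold - v[up]) / (v[up + 1] - v[up])
    t[up] + frac * (t[up + 1] - t[up])
  } else numeric(0)
  if (refractory_min > 0 && length(times) > 1) {
    keep <- times[1]
    for (x in times[-1]) if (x - keep[length(keep)] >= refractory_min)
      keep <- c(keep, x)
    times <- keep
  }
  structure(list(spike_times = times, threshold = threshold,
                 refractory_min = refractory_min),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$spike_times)
  cat(sprintf("Spike train: %d spikes (threshold %.3g V)\n", n, x$threshold))
  if (n >= 2)
    cat(sprintf("  mean ISI %.4g s (rate %.4g Hz)\n",
                mean(diff(x$spike_times)), 1 / mean(diff(x$spike_times))))
  invisible(x)
}

## Steady-state rate: discard the first `discard` fraction of the window,
## then 1/mean(ISI) of the remaining spikes (0 if fewer than 2).
steady_rate <- function(spike_times, t_span, discard = 0.2) {
  st <- spike_times[spike_times >= discard * t_span]
  if (length(st) < 2) return(0)
  1 / mean(diff(st))
}

#' Standard input-current grid for f-I curves
#'
#' Quasi-logarithmic grid spanning the 0.5-6 uA operating range of the
#' circuit, with a point near the class-1 rheobase so graded onset is
#' resolved.
#'
#' @return Numeric vector of amplitudes (A).
#' @export
standard_I_grid <- function() c(0.5, 0.9, 1.3, 2, 3, 4.5, 6) * 1e-6

#' Firing rate versus input current (f-I curve)
#'
#' Simulates a constant input at each amplitude and reports the steady
#' tonic rate (spikes after the first 20% of the window are used).
#'
#' @param p A [circuit_params()] object.
#' @param I_grid Input-current amplitudes (A), within the 0.5-6 uA
#'   operating range of the circuit.
#' @param T Simulation length per amplitude (s).
#' @param threshold Spike-detection threshold (V).
#' @param dt_out Output sampling (s).
#' @param ... Passed to [simulate_neuron()].
#' @return Data frame with columns `I_A` and `rate_Hz`.
#' @export
f_i_curve <- function(p, I_grid = standard_I_grid(), T = 3,
                      threshold = 0.25, dt_out = 1e-4, ...) {
  rates <- vapply(I_grid, function(I) {
    stim <- stimulus_program(baseline = I, t_max = T)
    tr <- simulate_neuron(p, stim, t_span = T, dt_out = dt_out, ...)
    steady_rate(detect_spikes(tr, threshold)$spike_times, T)
  }, 0.0)
  data.frame(I_A = I_grid, rate_Hz = rates)
}

#' Classify excitability from an f-I curve and an onset trace
#'
#' Decision rule:
#' * **class 3** if all spikes of a long (>= 3 s) constant step fall inside
#'   the onset window `T_onset`; subdivided into `"class3_phasic_bursting"`
#'   (>= 2 onset spikes) and `"class3_phasic_spiking"` (one spike);
#' * otherwise **class 2** if the smallest nonzero rate of the f-I curve
#'   exceeds `f_jump` times the rate at the top of the grid (an abrupt,
#'   high-frequency onset of firing);
#' * otherwise **class 1** (rate grows continuously from near zero).
#'
#' @param f_I Data frame from [f_i_curve()].
#' @param onset_trace A `coecn_trace` from a long constant step at the
#'   standard test amplitude.
#' @param T_onset Onset window (s) for the class-3 test.
#' @param f_jump Fraction of the top-of-grid rate that the smallest nonzero
#'   rate must exceed for class 2.
#' @param threshold Spike-detection threshold (V).
#' @param t_on Stimulus onset time within `onset_trace` (s).
#' @return One of `"class1"`, `"class2"`, `"class3_phasic_spiking"`,
#'   `"class3_phasic_bursting"`.
#' @export
classify_excitability <- function(f_I, onset_trace, T_onset = 0.3,
                                  f_jump = 0.6, threshold = 0.25,
                                  t_on = 0) {
  if (is.null(f_I) || !nrow(f_I)) stop("empty f-I curve")
  st <- detect_spikes(onset_trace, threshold)$spike_times
  t_end <- max(onset_trace$t)
  if (t_end - t_on < 3)
    warning("onset trace shorter than 3 s; class-3 call may be unreliable")
  if (length(st) >= 1 && all(st <= t_on + T_onset)) {
    return(if (length(st) >= 2) "class3_phasic_bursting"
           else "class3_phasic_spiking")
  }
  nz <- f_I$rate_Hz[f_I$rate_Hz > 0]
  if (!length(nz)) {
    if (!length(st)) stop("no excitability: no spikes in f-I grid or onset trace")
    nz <- 0
  }
  top <- f_I$rate_Hz[nrow(f_I)]
  if (length(nz) && top > 0 && min(nz) > f_jump * top) "class2" else "class1"
}

#' Spike-skipping statistics over an ensemble of traces
#'
#' With noisy input near threshold the neuron fires at a preserved base
#' period but randomly skips cycles, so interspike intervals (ISIs) cluster
#' at integer multiples of the base period. The base period is the mode of
#' the ISI histogram; each ISI is assigned its nearest integer multiple `k`
#' of the base period (within `tol` relative tolerance); `skip_fraction` is
#' the fraction with `k >= 2`, and the multimodality score is the fraction
#' of ISIs within tolerance of any integer multiple.
#'
#' @param traces A list of `coecn_trace` objects (or `spike_train`s).
#' @param threshold Spike-detection threshold (V).
#' @param tol Relative tolerance for integer-multiple assignment.
#' @return List with `base_frequency_Hz`, `skip_fraction`, `multimodality`
#'   and the pooled `isis`.
#' @export
skipping_statistics <- function(traces, threshold = 0.25, tol = 0.25) {
  isis <- unlist(lapply(traces, function(tr) {
    st <- if (inherits(tr, "spike_train")) tr$spike_times
          else detect_spikes(tr, threshold)$spike_times
    diff(st)
  }))
  if (length(isis) < 9)
    stop("too few spikes for skipping statistics (need >= 10 spikes)")
  ## mode of the ISI histogram via a fine kernel density; a perfectly
  ## periodic train collapses to a single unique ISI, which density()
  ## handles but reports
  d <- suppressWarnings(stats::density(isis, n = 512))
  base_period <- d$x[which.max(d$y)]
  k <- pmax(1L, as.integer(round(isis / base_period)))
  ok <- abs(isis - k * base_period) <= tol * base_period
  list(base_frequency_Hz = 1 / base_period,
       skip_fraction = mean(k[ok] >= 2),
       multimodality = mean(ok),
       isis = isis)
}

#' Instantaneous supply power of the c-OECN
#'
#' Bookkeeping: `P(t) = |E_Na * I_Na| + |E_K * I_K| + P_amp`, where the
#' amplifier rail power is the high rail voltage times the amplifier
#' output-stage current, modeled as the Na-OECT gate charging current
#' `C_g_Na * |d(amplifier output)/dt|`.
#'
#' @param trace A `coecn_trace` from [simulate_neuron()].
#' @param p The [circuit_params()] used for the run.
#' @return Numeric vector, watts, aligned with `trace$t`.
#' @export
power_trace <- function(trace, p) {
  v_amp <- amplifier_output(trace$V_mem, p$amplifier)
  damp <- c(0, diff(v_amp)) / c(1, diff(trace$t))
  p_amp <- p$amplifier$rail_high * p$C_g_Na * abs(damp)
  abs(p$E_Na * trace$I_Na) + abs(p$E_K * trace$I_K) + p_amp
}

#' Energy metrics of steady tonic spiking
#'
#' Extracts one full steady period (between the two last detected spikes)
#' and reports the peak instantaneous supply power over that period and the
#' energy per spike, the integral of the power over the period (trapezoidal
#' rule).
#'
#' @param trace A `coecn_trace` in steady tonic spiking.
#' @param p The [circuit_params()] used for the run.
#' @param threshold Spike-detection threshold (V).
#' @return List with `peak_power_W` and `energy_per_spike_J`.
#' @export
energy_metrics <- function(trace, p, threshold = 0.25) {
  st <- detect_spikes(trace, threshold)$spike_times
  if (length(st) < 3)
    stop("no steady period found: need at least 3 spikes")
  t0 <- st[length(st) - 1]; t1 <- st[length(st)]
  sel <- trace$t >= t0 & trace$t <= t1
  P <- power_trace(trace, p)[sel]
  tt <- trace$t[sel]
  list(peak_power_W = max(P),
       energy_per_spike_J = sum(diff(tt) * (P[-1] + P[-length(P)]) / 2))
}

#' Run the neurocomputational feature battery
#'
#' Exercises the circuit with the standard protocol set and applies
#' per-feature decision rules:
#' tonic (steady rate under a constant step), latency (first-spike delay
#' decreasing with amplitude), integration (paired subthreshold pulses spike
#' at a short gap but not a long one), refractoriness (the second of two
#' suprathreshold pulses fails at short gaps), rebound (a spike within
#' `rebound_window` after release of a negative pulse), accommodation (a
#' step spikes while an equal-endpoint slow ramp does not), threshold
#' variability (a preceding negative pulse flips the outcome of an identical
#' test pulse) and the excitability class from the f-I curve plus onset
#' trace. Failures are reported per feature, never as a global error.
#'
#' @param p A [circuit_params()] object.
#' @param I_test Standard test amplitude (A).
#' @param period Expected tonic period (s); sets pulse widths and gaps.
#' @param threshold Spike-detection threshold (V).
#' @param T_tonic Length of the tonic run (s).
#' @param rebound_window Window after release for a rebound spike (s).
#' @param f_I Optional precomputed f-I curve (data frame); computed on a
#'   3-point grid when omitted.
#' @param dt_out Output sampling (s).
#' @param sub_amp Subthreshold pulse amplitude (A) for integration; defaults
#'   to `0.9 * I_test`.
#' @return An object of class `"feature_report"`.
#' @export
feature_battery <- function(p, I_test = 2e-6, period = 0.2,
                            threshold = 0.25, T_tonic = 4,
                            rebound_window = 0.2, f_I = NULL,
                            dt_out = 1e-4, sub_amp = NULL) {
  refr <- 0.1 * period
  run <- function(stim, T) simulate_neuron(p, stim, t_span = T,
                                           dt_out = dt_out)
  n_spikes <- function(stim, T, after = 0) {
    st <- detect_spikes(run(stim, T), threshold, refr)$spike_times
    sum(st >= after)
  }
  first_spike <- function(stim, T, t_on) {
    st <- detect_spikes(run(stim, T), threshold, refr)$spike_times
    st <- st[st >= t_on]
    if (length(st)) st[1] - t_on else NA_real_
  }

  ## tonic
  tr_tonic <- run(stimulus_program(baseline = I_test, t_max = T_tonic),
                  T_tonic)
  st_tonic <- detect_spikes(tr_tonic, threshold, refr)$spike_times
  rate <- steady_rate(st_tonic, T_tonic)
  tonic <- rate > 0

  ## latency: first-spike delay at 1x and 1.5x the test amplitude
  t_on <- 2 * period
  Tl <- t_on + 4 * period
  lat1 <- first_spike(protocol_library("step", amplitude = I_test,
                                       t_on = t_on, t_max = Tl), Tl, t_on)
  lat2 <- first_spike(protocol_library("step", amplitude = 1.5 * I_test,
                                       t_on = t_on, t_max = Tl), Tl, t_on)
  latency <- is.finite(lat1) && is.finite(lat2) && lat2 < lat1

  ## integration: paired subthreshold pulses, short vs long gap
  if (is.null(sub_amp)) sub_amp <- 0.9 * I_test
  w <- period / 4
  Ti <- t_on + 8 * period
  short_gap <- period / 10; long_gap <- 2 * period
  n_int_s <- n_spikes(protocol_library("paired_pulse", amplitude = sub_amp,
                                       width = w, delta = short_gap,
                                       t_on = t_on, t_max = Ti), Ti)
  n_int_l <- n_spikes(protocol_library("paired_pulse", amplitude = sub_amp,
                                       width = w, delta = long_gap,
                                       t_on = t_on, t_max = Ti), Ti)
  single <- n_spikes(protocol_library("step", amplitude = sub_amp,
                                      t_on = t_on, t_max = t_on + w + 0.5),
                     t_on + w + 0.5)
  integration <- (single == 0) && (n_int_s >= 1) && (n_int_l == 0)
  crit_gap <- if (integration) short_gap else NA_real_

  ## refractoriness: two suprathreshold pulses; short gap suppresses the 2nd
  supra <- 2 * I_test
  n_ref_s <- n_spikes(protocol_library("paired_pulse", amplitude = supra,
                                       width = w, delta = period / 10,
                                       t_on = t_on, t_max = Ti), Ti)
  n_ref_l <- n_spikes(protocol_library("paired_pulse", amplitude = supra,
                                       width = w, delta = 2 * period,
                                       t_on = t_on, t_max = Ti), Ti)
  refractoriness <- (n_ref_s == 1) && (n_ref_l >= 2)
  refractory_period <- if (refractoriness) period / 10 else NA_real_

  ## rebound: negative pulse release
  Tr <- t_on + 6 * period
  tr_reb <- run(protocol_library("neg_release", neg_amplitude = -I_test,
                                 width = 2 * period, t_on = t_on,
                                 t_max = Tr), Tr)
  st_reb <- detect_spikes(tr_reb, threshold, refr)$spike_times
  release <- t_on + 2 * period
  rebound <- any(st_reb > release & st_reb <= release + rebound_window)

  ## accommodation: slow ramp vs step to the same endpoint
  ramp_T <- 10 * period
  Ta <- t_on + ramp_T + 4 * period
  pr <- protocol_library("ramp_vs_step", amplitude = I_test, t_on = t_on,
                         ramp_duration = ramp_T, t_max = Ta)
  n_ramp <- n_spikes(pr$ramp, Ta)
  n_step <- n_spikes(pr$step, Ta)
  accommodation <- (n_step >= 1) && (n_ramp == 0)

  ## threshold variability: negative conditioning changes the outcome
  tv_amp <- 0.95 * I_test
  n_tv0 <- n_spikes(protocol_library("step", amplitude = tv_amp,
                                     t_on = t_on, t_max = t_on + w + 0.5),
                    t_on + w + 0.5)
  n_tv1 <- n_spikes(protocol_library("neg_then_test", amplitude = tv_amp,
                                     neg_amplitude = -I_test, width = w,
                                     delta = period / 10, t_on = t_on,
                                     t_max = Ti), Ti)
  threshold_variability <- (n_tv0 != n_tv1)

  ## resonance: paired suprathreshold-but-brief pulses at several gaps;
  ## "resonant" if the second spike succeeds in a band of gaps only
  gaps <- period * c(0.1, 0.5, 1, 2)
  res_counts <- vapply(gaps, function(d)
    n_spikes(protocol_library("paired_pulse", amplitude = supra, width = w,
                              delta = d, t_on = t_on, t_max = Ti), Ti), 0L)
  resonance <- any(res_counts >= 2) && any(res_counts < 2)
  preferred_interval <- if (resonance) gaps[which.max(res_counts)] else NA_real_

  ## excitability class
  if (is.null(f_I))
    f_I <- f_i_curve(p, I_grid = standard_I_grid(), T = 2,
                     threshold = threshold, dt_out = dt_out)
  onset <- run(stimulus_program(baseline = I_test, t_max = 3.5), 3.5)
  cls <- tryCatch(classify_excitability(f_I, onset, threshold = threshold),
                  error = function(e) NA_character_)

  structure(list(
    tonic = tonic, rate_Hz = rate,
    latency = latency, latency_s = c(lat1 = lat1, lat2 = lat2),
    integration = integration, critical_gap_s = crit_gap,
    refractoriness = refractoriness, refractory_period_s = refractory_period,
    resonance = resonance, preferred_interval_s = preferred_interval,
    threshold_variability = threshold_variability,
    rebound = rebound, accommodation = accommodation,
    excitability_class = cls, f_I = f_I),
    class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("c-OECN feature report\n")
  flags <- c(tonic = x$tonic, latency = x$latency,
             integration = x$integration,
             refractoriness = x$refractoriness, resonance = x$resonance,
             threshold_variability = x$threshold_variability,
             rebound = x$rebound, accommodation = x$accommodation)
  for (nm in names(flags))
    cat(sprintf("  %-22s %s\n", nm, ifelse(isTRUE(flags[[nm]]), "yes", "no")))
  cat(sprintf("  tonic rate: %.3g Hz\n", x$rate_Hz))
  cat(sprintf("  excitability class: %s\n", x$excitability_class))
  invisible(x)
}
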