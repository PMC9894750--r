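#' Excitability-class scan over the potassium supply voltage
#'
#' Re-classifies the neuron at each value of `E_K`. Lowering `E_K` makes the
#' K-OECT turn on earlier in the spike cycle, moving the neuron from class 1
#' through class 2 to class 3 (phasic) behaviour.
#'
#' @param base A [circuit_params()] object.
#' @param E_K_grid Values of `E_K` (V), within \[-0.1, 0\].
#' @param I_test Test amplitude (A) for the onset trace.
#' @param I_grid f-I grid (A).
#' @param threshold Spike-detection threshold (V).
#' @param keep_traces If `TRUE`, archive the onset traces in the result.
#' @return Data frame with `E_K_V` and `label`; traces in attribute
#'   `"traces"` when requested.
#' @export
run_class_switch_scan <- function(base, E_K_grid, I_test = 2e-6,
                                  I_grid = standard_I_grid(),
                                  threshold = 0.25, keep_traces = FALSE) {
  stopifnot(all(E_K_grid >= -0.1), all(E_K_grid <= 0))
  traces <- list()
  labels <- vapply(E_K_grid, function(ek) {
    p <- base
    p$E_K <- ek
    fi <- f_i_curve(p, I_grid = I_grid, T = 2, threshold = threshold)
    onset <- simulate_neuron(p, stimulus_program(baseline = I_test,
                                                 t_max = 3.5),
                             t_span = 3.5)
    if (keep_traces) traces[[length(traces) + 1]] <<- onset
    classify_excitability(fi, onset, threshold = threshold)
  }, "")
  out <- data.frame(E_K_V = E_K_grid, label = labels)
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Excitability-class scan over calcium concentration
#'
#' Routes Ca2+ to the K-OECT electrolyte: the threshold shift
#' [effective_vk()] makes the potassium branch turn on earlier, which is
#' equivalent to lowering `E_K`. A slow increase of Ca2+ therefore reproduces
#' the class 1 to phasic transition of [run_class_switch_scan()].
#'
#' @param base A [circuit_params()] object.
#' @param ca_grid Ca2+ concentrations (mM).
#' @param dVK_coeff Threshold shift per mM (V/mM, negative).
#' @inheritParams run_class_switch_scan
#' @return Data frame with `ca_mM`, `V_K_eff_V` and `label`.
#' @export
run_ca_modulation <- function(base, ca_grid, dVK_coeff = -0.01,
                              I_test = 2e-6,
                              I_grid = standard_I_grid(),
                              threshold = 0.25) {
  stopifnot(all(ca_grid >= 0))
  res <- lapply(ca_grid, function(ca) {
    p <- base
    p$k_electrolyte <- electrolyte(
      modulators = list(modulator("Ca", conc_mM = ca,
                                  dVK_coeff = dVK_coeff)),
      target = "K_OECT")
    fi <- f_i_curve(p, I_grid = I_grid, T = 2, threshold = threshold)
    onset <- simulate_neuron(p, stimulus_program(baseline = I_test,
                                                 t_max = 3.5),
                             t_span = 3.5)
    list(vk = effective_vk(p$k_params, p$k_electrolyte),
         label = classify_excitability(fi, onset, threshold = threshold))
  })
  data.frame(ca_mM = ca_grid,
             V_K_eff_V = vapply(res, `[[`, 0.0, "vk"),
             label = vapply(res, `[[`, "", "label"))
}

#' Event-based concentration scan (chemical sensing)
#'
#' Simulates the neuron at each concentration of an analyte routed to the
#' Na-OECT electrolyte and records whether it spikes (at least `min_spikes`
#' spikes in the analysis window). The reported threshold follows the
#' convention: the largest non-spiking grid concentration when the neuron
#' spikes at high concentrations, and the lowest non-spiking concentration
#' when it spikes at low concentrations.
#'
#' @param base A [circuit_params()] object (a sensing calibration).
#' @param rule A list describing the scan: `analyte` (name), `grid`
#'   (ascending concentrations), `unit` (`"mM"` or `"uM"`), and `make_electrolyte`,
#'   a function of one concentration returning the Na-OECT [electrolyte()].
#' @param I_test Input current (A).
#' @param window Analysis window (s).
#' @param min_spikes Spike count defining "spiking".
#' @param threshold Spike-detection threshold (V).
#' @return An object of class `"sensing_report"`: data frame of
#'   `concentration`, `n_spikes`, `spiking` plus attributes `analyte`,
#'   `unit`, `threshold_concentration` and `convention`.
#' @export
run_concentration_scan <- function(base, rule, I_test = 2e-6, window = 3,
                                   min_spikes = 3, threshold = 0.25) {
  stopifnot(!is.unsorted(rule$grid))
  res <- vapply(rule$grid, function(conc) {
    p <- base
    p$na_electrolyte <- rule$make_electrolyte(conc)
    ## start from the quiescent state of the modulated circuit; when the
    ## modulation leaves no stable rest, start from the leak reversal
    init <- tryCatch({
      rs <- resting_state(p)
      c(V_mem = rs$V_mem, V_gk = rs$V_gk)
    }, error = function(e) c(V_mem = p$E_L, V_gk = p$E_L))
    tr <- suppressWarnings(
      simulate_neuron(p, stimulus_program(baseline = I_test,
                                          t_max = window),
                      t_span = window, init = init))
    length(detect_spikes(tr, threshold)$spike_times)
  }, 0L)
  spiking <- res >= min_spikes
  non <- rule$grid[!spiking]
  spk <- rule$grid[spiking]
  if (length(non) == 0) {
    thr <- NA_real_; conv <- "spiking at all grid points"
  } else if (length(spk) && max(spk) > max(non)) {
    thr <- max(non); conv <- "largest non-spiking concentration"
  } else {
    thr <- min(non); conv <- "lowest non-spiking concentration"
  }
  out <- data.frame(concentration = rule$grid, n_spikes = res,
                    spiking = spiking)
  attr(out, "analyte") <- rule$analyte
  attr(out, "unit") <- rule$unit
  attr(out, "threshold_concentration") <- thr
  attr(out, "convention") <- conv
  class(out) <- c("sensing_report", class(out))
  out
}

#' @export
print.sensing_report <- function(x, ...) {
  cat(sprintf("Event sensing: %s (%s)\n", attr(x, "analyte"), attr(x, "unit")))
  print.data.frame(x)
  cat(sprintf("  threshold: %.4g %s (%s)\n",
              attr(x, "threshold_concentration"), attr(x, "unit"),
              attr(x, "convention")))
  invisible(x)
}

#' Noise-driven stochastic spike skipping
#'
#' Runs a seeded ensemble of simulations at a subthreshold mean input with
#' Ornstein-Uhlenbeck current noise of increasing amplitude and collects
#' [skipping_statistics()] per noise level. Near the subcritical threshold
#' the neuron fires on a preserved base period but randomly skips cycles;
#' more noise increases the skipped fraction while the base frequency stays
#' put.
#'
#' @param base A [circuit_params()] object; the default study setting is
#'   the class-2 neuron (`config_A(E_K = -0.065)`).
#' @param I_mean Mean input current (A), subthreshold for `base`.
#' @param sigmas Noise standard deviations (A), increasing.
#' @param n_seeds Ensemble size per noise level.
#' @param seed0 Base seed; run `j` of level `i` uses
#'   `seed0 + 1000 * i + j`.
#' @param T Simulation length per run (s).
#' @param tau OU correlation time (s).
#' @param threshold Spike-detection threshold (V).
#' @return Data frame with one row per noise level: `sigma_A`,
#'   `base_frequency_Hz`, `skip_fraction`, `multimodality`, `n_isis`.
#' @export
run_skipping_ensemble <- function(base = config_A(E_K = -0.065),
                                  I_mean = 1.8e-6,
                                  sigmas = c(1e-7, 3.5e-7, 6e-7),
                                  n_seeds = 7, seed0 = 1L, T = 5,
                                  tau = 0.01, threshold = 0.25) {
  rows <- lapply(seq_along(sigmas), function(i) {
    traces <- lapply(seq_len(n_seeds), function(j) {
      stim <- stimulus_program(baseline = I_mean, t_max = T,
                               noise = list(model = "OU", sigma = sigmas[i],
                                            tau = tau,
                                            seed = seed0 + 1000L * i + j))
      simulate_neuron(base, stim, t_span = T, dt_out = 2e-4)
    })
    s <- skipping_statistics(traces, threshold = threshold)
    data.frame(sigma_A = sigmas[i], base_frequency_Hz = s$base_frequency_Hz,
               skip_fraction = s$skip_fraction,
               multimodality = s$multimodality, n_isis = length(s$isis))
  })
  do.call(rbind, rows)
}

#' GABA step inhibition
#'
#' Simulates tonic spiking, then applies GABA to the Na-OECT electrolyte
#' from `t_on` (concentrations are piecewise-constant per segment, so the
#' run is split at `t_on` and the state carried over). GABA attenuates the
#' antiambipolar peak current and shifts its peak voltage down, which
#' suppresses the sodium spike and hence all spiking. A third segment with
#' GABA removed can be appended to show reversibility.
#'
#' @param base A [circuit_params()] object.
#' @param gaba_step GABA concentration applied at `t_on` (mM).
#' @param t_on Application time (s).
#' @param t_off Optional wash-out time (s); `NA` to keep GABA on.
#' @param t_end Total simulated time (s).
#' @param I_test Input current (A).
#' @param coeffs GABA coefficients: list with `dVP_coeff` (V/mM) and
#'   `peak_atten` (1/mM); defaults are the reference calibration.
#' @param threshold Spike-detection threshold (V).
#' @param washout_noise_sigma OU noise amplitude (A) added to the input
#'   after wash-out. The restored circuit is bistable at the test input (a
#'   stable depolarized equilibrium coexists with the spiking limit cycle)
#'   and the GABA-inhibited state lies inside the quiescent basin, so a
#'   noiseless continuation stays silent; a modest seeded noise kicks the
#'   state back onto the limit cycle, making the run reproducible.
#' @param seed Seed for the wash-out noise.
#' @return List with the stitched `trace`, `inhibited` (no spikes after one
#'   period past `t_on` while spikes were present before) and `recovered`
#'   (spiking resumed after wash-out, when `t_off` is given).
#' @export
run_gaba_inhibition <- function(base, gaba_step = 1, t_on = 2, t_off = NA,
                                t_end = 6, I_test = 2e-6,
                                coeffs = list(dVP_coeff = -0.05,
                                              peak_atten = 0.35),
                                threshold = 0.25,
                                washout_noise_sigma = 3e-7, seed = 1L) {
  stopifnot(t_on > 0, t_end > t_on)
  stim <- function(T, noise = NULL)
    stimulus_program(baseline = I_test, t_max = T, noise = noise)
  tr1 <- simulate_neuron(base, stim(t_on), t_span = t_on)
  p2 <- base
  p2$na_electrolyte <- electrolyte(
    modulators = list(modulator("GABA", conc_mM = gaba_step,
                                dVP_coeff = coeffs$dVP_coeff,
                                peak_atten = coeffs$peak_atten)),
    target = "Na_OECT")
  n <- length(tr1$t)
  init <- c(V_mem = tr1$V_mem[n], V_gk = tr1$V_gk[n])
  t2_end <- if (is.na(t_off)) t_end else t_off
  tr2 <- simulate_neuron(p2, stim(t2_end - t_on), t_span = t2_end - t_on,
                         init = init)
  parts <- list(tr1, tr2)
  offsets <- c(0, t_on)
  if (!is.na(t_off)) {
    n2 <- length(tr2$t)
    noise3 <- if (washout_noise_sigma > 0)
      list(model = "OU", sigma = washout_noise_sigma, tau = 0.01,
           seed = as.integer(seed)) else NULL
    tr3 <- simulate_neuron(base, stim(t_end - t_off, noise3),
                           t_span = t_end - t_off,
                           init = c(V_mem = tr2$V_mem[n2],
                                    V_gk = tr2$V_gk[n2]))
    parts <- c(parts, list(tr3))
    offsets <- c(offsets, t_off)
  }
  stitch <- function(field) unlist(lapply(seq_along(parts), function(i) {
    x <- parts[[i]][[field]]
    if (i > 1) x[-1] else x
  }))
  tt <- unlist(lapply(seq_along(parts), function(i) {
    x <- parts[[i]]$t + offsets[i]
    if (i > 1) x[-1] else x
  }))
  trace <- structure(list(t = tt, V_mem = stitch("V_mem"),
                          V_gk = stitch("V_gk"), I_in = stitch("I_in"),
                          I_Na = stitch("I_Na"), I_K = stitch("I_K"),
                          I_leak = stitch("I_leak"),
                          meta = tr1$meta),
                     class = "coecn_trace")
  st <- detect_spikes(trace, threshold)$spike_times
  before <- st[st < t_on]
  period <- if (length(before) >= 2) mean(diff(before)) else 0.5
  after <- st[st > t_on + period & st <= t2_end]
  inhibited <- length(before) >= 2 && length(after) == 0
  recovered <- if (is.na(t_off)) NA else
    length(st[st > t_off + period]) >= 1
  list(trace = trace, inhibited = inhibited, recovered = recovered,
       spike_times = st)
}
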