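## synthetic trace helper: triangular (sawtooth) membrane waveform
sawtooth_trace <- function(freq = 5, T = 3, dt = 1e-4, lo = 0.15, hi = 0.35) {
  t <- seq(0, T, by = dt)
  phase <- (t * freq) %% 1
  v <- ifelse(phase < 0.5, lo + (hi - lo) * 2 * phase,
              hi - (hi - lo) * 2 * (phase - 0.5))
  structure(list(t = t, V_mem = v, V_gk = v * 0, I_in = v * 0,
                 I_Na = v * 0, I_K = v * 0, I_leak = v * 0,
                 meta = list(dt_out = dt, method = "synthetic")),
            class = "coecn_trace")
}

test_that("detect_spikes counts threshold crossings of a known waveform", {
  tr <- sawtooth_trace(freq = 5, T = 3)
  st <- detect_spikes(tr, threshold = 0.25)
  expect_length(st$spike_times, 15)  # 5 Hz for 3 s
  expect_true(all(diff(st$spike_times) > 0))
  ## constant trace below threshold: no spikes, not an error
  flat <- sawtooth_trace(lo = 0.1, hi = 0.2)
  expect_length(detect_spikes(flat, 0.25)$spike_times, 0)
})

test_that("detect_spikes is monotone in threshold and respects refractoriness", {
  p <- config_A()
  tr <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 2),
                        t_span = 2)
  counts <- vapply(c(0.20, 0.25, 0.30, 0.33, 0.36), function(th)
    length(detect_spikes(tr, th)$spike_times), 0L)
  expect_true(all(diff(counts) <= 0))
  ## refractory filter never increases the count and enforces separation
  st <- detect_spikes(tr, 0.25, refractory_min = 0.15)$spike_times
  expect_true(all(diff(st) >= 0.15))
})

test_that("spike times interpolate consistently across sampling densities", {
  t1 <- sawtooth_trace(freq = 5, T = 2, dt = 2e-4)
  t2 <- sawtooth_trace(freq = 5, T = 2, dt = 1e-4)
  s1 <- detect_spikes(t1, 0.25)$spike_times
  s2 <- detect_spikes(t2, 0.25)$spike_times
  expect_length(s1, length(s2))
  expect_lt(max(abs(s1 - s2)), 0.5 * 2e-4)
})

test_that("f-I curve is non-negative, consistent with detect_spikes", {
  p <- config_A()
  fi <- f_i_curve(p, I_grid = c(0.5, 2, 4) * 1e-6, T = 2)
  expect_true(all(fi$rate_Hz >= 0))
  expect_equal(fi$rate_Hz[1], 0)  # below rheobase
  ## internal consistency at the largest amplitude
  tr <- simulate_neuron(p, stimulus_program(baseline = 4e-6, t_max = 2),
                        t_span = 2)
  st <- detect_spikes(tr, 0.25)$spike_times
  st <- st[st >= 0.4]
  expect_equal(fi$rate_Hz[3], 1 / mean(diff(st)), tolerance = 0.01)
})

test_that("excitability classifier implements the decision rules", {
  fi_grad <- data.frame(I_A = 1:5 * 1e-6, rate_Hz = c(0, 1, 3, 5, 6))
  fi_jump <- data.frame(I_A = 1:5 * 1e-6, rate_Hz = c(0, 0, 5.5, 6, 6.5))
  long_tonic <- sawtooth_trace(freq = 5, T = 3.5)
  expect_equal(classify_excitability(fi_grad, long_tonic), "class1")
  expect_equal(classify_excitability(fi_jump, long_tonic), "class2")
  ## all spikes inside the onset window of a >= 3 s step: class 3
  onset_burst <- sawtooth_trace(freq = 20, T = 3.5)
  onset_burst$V_mem[onset_burst$t > 0.25] <- 0.15
  expect_equal(classify_excitability(fi_jump, onset_burst),
               "class3_phasic_bursting")
  one_spike <- sawtooth_trace(freq = 5, T = 3.5)
  one_spike$V_mem[one_spike$t > 0.12] <- 0.15
  expect_equal(classify_excitability(fi_jump, one_spike),
               "class3_phasic_spiking")
  none <- sawtooth_trace(lo = 0.1, hi = 0.2, T = 3.5)
  expect_error(classify_excitability(
    data.frame(I_A = 1e-6, rate_Hz = 0), none), "no excitability")
})

test_that("classifier label is invariant to trace resampling", {
  p <- config_A()
  fi <- f_i_curve(p, I_grid = c(0.5, 0.9, 1.3, 2, 3, 4.5, 6) * 1e-6, T = 2)
  on1 <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 3.5),
                         t_span = 3.5, dt_out = 2e-4)
  on2 <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 3.5),
                         t_span = 3.5, dt_out = 1e-4)
  expect_identical(classify_excitability(fi, on1),
                   classify_excitability(fi, on2))
})

test_that("skipping statistics recover constructed skip patterns", {
  ## noiseless periodic train: no skips, full multimodality
  st_per <- structure(list(spike_times = seq(0.1, 5, by = 0.2),
                           threshold = 0.25, refractory_min = 0),
                      class = "spike_train")
  s <- skipping_statistics(list(st_per))
  expect_equal(s$skip_fraction, 0)
  expect_equal(s$multimodality, 1)
  expect_equal(s$base_frequency_Hz, 5, tolerance = 0.05)
  ## deleting every 3rd spike doubles 19 of the remaining 39 ISIs
  full <- seq(0.1, 12, by = 0.2)
  thinned <- full[-seq(3, length(full), by = 3)]
  st_thin <- structure(list(spike_times = thinned, threshold = 0.25,
                            refractory_min = 0), class = "spike_train")
  s2 <- skipping_statistics(list(st_thin))
  expect_equal(s2$skip_fraction, 19 / 39, tolerance = 1e-8)
  expect_equal(s2$base_frequency_Hz, 5, tolerance = 0.05)
  ## shuffled-ISI surrogate destroys integer-multiple structure
  set.seed(1)
  jit <- cumsum(sample(c(rep(0.2, 20), runif(20, 0.05, 0.35))))
  st_shuf <- structure(list(spike_times = jit, threshold = 0.25,
                            refractory_min = 0), class = "spike_train")
  s3 <- skipping_statistics(list(st_shuf))
  expect_lt(s3$multimodality, s2$multimodality)
  expect_error(skipping_statistics(list(structure(
    list(spike_times = c(1, 2), threshold = 0.25, refractory_min = 0),
    class = "spike_train"))), "too few")
})

test_that("energy metrics integrate a rectangular current analytically", {
  ## synthetic trace: I_Na = 10 uA for 20 ms of a 100 ms period, all else 0
  dt <- 1e-4
  t <- seq(0, 0.5, by = dt)
  v <- 0.15 + 0.2 * (t %% 0.1 < 0.02)       # crosses 0.25 during the pulse
  ina <- 1e-5 * (t %% 0.1 < 0.02)
  tr <- structure(list(t = t, V_mem = v, V_gk = v * 0, I_in = v * 0,
                       I_Na = ina, I_K = v * 0, I_leak = v * 0,
                       meta = list()), class = "coecn_trace")
  p <- config_A()
  p$C_g_Na <- 0  # isolate the supply term
  em <- energy_metrics(tr, p, threshold = 0.25)
  ## |E_Na * I_Na| = 0.5 V * 10 uA = 5 uW for 20 ms -> 100 nJ per period
  expect_equal(em$peak_power_W, 5e-6, tolerance = 1e-6)
  expect_equal(em$energy_per_spike_J, 1e-7, tolerance = 0.02)
  ## degenerate all-zero currents
  tr0 <- tr; tr0$I_Na <- tr$I_Na * 0
  em0 <- energy_metrics(tr0, p, threshold = 0.25)
  expect_equal(em0$peak_power_W, 0)
  expect_equal(em0$energy_per_spike_J, 0)
})

test_that("feature battery reports tonic class-1 spiking for the reference neuron", {
  rep <- feature_battery(config_A(), T_tonic = 3)
  expect_true(rep$tonic)
  expect_equal(rep$rate_Hz, 5, tolerance = 0.05)
  expect_true(rep$latency)
  expect_equal(rep$excitability_class, "class1")
})

test_that("a dead circuit produces an all-negative feature report", {
  p <- config_A()
  p$na_params$I_peak0 <- 1e-18   # sodium branch effectively removed
  p$na_params$k_peak <- 0
  p$G_L <- 1e-4                  # leak keeps passive charging subthreshold
  rep <- feature_battery(p, T_tonic = 1)
  expect_false(rep$tonic)
  expect_equal(rep$rate_Hz, 0)
  for (f in c("latency", "integration", "refractoriness", "rebound",
              "accommodation"))
    expect_false(isTRUE(rep[[f]]))
  expect_true(is.na(rep$excitability_class))
})

test_that("feature battery validates its detectors on the HH oracle", {
  p <- hh_params()
  ## HH at ms time scale: period ~ 15 ms at 10 uA/cm^2
  run <- function(stim, T) hh_simulate(p, stim, t_span = T)
  t_on <- 0.03
  ## tonic
  tr <- run(stimulus_program(baseline = 10e-6, t_max = 0.4), 0.4)
  st <- detect_spikes(tr, 0)$spike_times
  expect_gte(length(st), 10)
  ## latency decreasing in amplitude
  lat <- vapply(c(8e-6, 20e-6), function(a) {
    s <- protocol_library("step", amplitude = a, t_on = t_on, t_max = 0.2)
    det <- detect_spikes(run(s, 0.2), 0)$spike_times
    det[det >= t_on][1] - t_on
  }, 0.0)
  expect_true(all(is.finite(lat)))
  expect_lt(lat[2], lat[1])
  ## refractoriness: second suprathreshold pulse fails at short gaps
  n_at_gap <- function(d) {
    s <- protocol_library("paired_pulse", amplitude = 15e-6, width = 0.002,
                          delta = d, t_on = t_on, t_max = 0.12)
    length(detect_spikes(run(s, 0.12), 0)$spike_times)
  }
  expect_equal(n_at_gap(0.003), 1)   # inside refractory period
  expect_equal(n_at_gap(0.03), 2)    # fully recovered
})
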