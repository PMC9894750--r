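test_that("circuit_rhs satisfies Kirchhoff's current law identically", {
  p <- config_A()
  stim <- stimulus_program(baseline = 2e-6, t_max = 1)
  ## KCL residual recomputed independently from the returned currents
  for (st in list(c(V_mem = 0.175, V_gk = 0.175),
                  c(V_mem = 0.30, V_gk = 0.22),
                  c(V_mem = 0.10, V_gk = 0.28))) {
    r <- circuit_rhs(as.list(st), 0.5, p, stim)
    resid <- r$dV_mem * (p$C_mem + p$C_int) -
      (r$I_in + r$I_Na - r$I_K - r$I_leak)
    expect_lt(abs(resid), 1e-9 * max(abs(r$I_in), abs(r$I_Na), 1e-12))
  }
  expect_error(circuit_rhs(list(V_mem = NaN, V_gk = 0), 0, p), "V_mem")
})

test_that("KCL holds along a simulated trajectory at every sample", {
  p <- config_A()
  stim <- stimulus_program(baseline = 2e-6, t_max = 0.6)
  tr <- simulate_neuron(p, stim, t_span = 0.6, dt_out = 1e-4)
  ## recompute all currents from the stored states and compare with trace
  dev <- coecn:::effective_devices(p)
  I_Na2 <- antiambipolar_current(amplifier_output(tr$V_mem, p$amplifier),
                                 pmax(p$E_Na - tr$V_mem, 0), dev$na)
  I_K2 <- oect_current(tr$V_gk - p$E_K, pmax(tr$V_mem - p$E_K, 0), dev$k)
  expect_equal(tr$I_Na, I_Na2, tolerance = 1e-12)
  expect_equal(tr$I_K, I_K2, tolerance = 1e-12)
})

test_that("zero effective drain bias kills the sodium current", {
  p <- config_A()
  r <- circuit_rhs(list(V_mem = p$E_Na, V_gk = 0.2), 0, p, NULL)
  expect_equal(r$I_Na, 0)
})

test_that("resting state sits at 175 mV, is stable and persists", {
  p <- config_A()
  rs <- resting_state(p)
  expect_equal(rs$V_mem, 0.175, tolerance = 1e-4)
  expect_equal(rs$V_gk, rs$V_mem)
  expect_true(all(Re(attr(rs, "eigenvalues")) < 0))
  ## rhs vanishes at the fixed point
  r <- circuit_rhs(rs, 0, p, NULL)
  expect_lt(abs(r$dV_mem), 1e-6)
  expect_lt(abs(r$dV_gk), 1e-9)
  ## fed back into a zero-input simulation the state stays put
  tr <- simulate_neuron(p, NULL, t_span = 10, dt_out = 1e-3)
  expect_lt(max(abs(tr$V_mem - rs$V_mem)), 1e-3)
})

test_that("a leak-dominated circuit rests at the leak reversal", {
  p <- config_A()
  p$G_L <- 1  # 1 S swamps every device current
  expect_equal(resting_state(p)$V_mem, p$E_L, tolerance = 1e-4)
})

test_that("subthreshold perturbations decay back to rest without spikes", {
  p <- config_A()
  rs <- resting_state(p)
  tr <- simulate_neuron(p, NULL, t_span = 3,
                        init = c(V_mem = rs$V_mem + 0.02, V_gk = rs$V_gk))
  expect_length(detect_spikes(tr, 0.25)$spike_times, 0)
  expect_lt(abs(tr$V_mem[length(tr$V_mem)] - rs$V_mem), 1e-4)
})

test_that("identical configuration and seed give bit-identical traces", {
  p <- config_A()
  stim1 <- stimulus_program(baseline = 2e-6, t_max = 1,
                            noise = list(model = "OU", sigma = 2e-7,
                                         tau = 0.01, seed = 12))
  stim2 <- stimulus_program(baseline = 2e-6, t_max = 1,
                            noise = list(model = "OU", sigma = 2e-7,
                                         tau = 0.01, seed = 12))
  tr1 <- simulate_neuron(p, stim1, t_span = 1)
  tr2 <- simulate_neuron(p, stim2, t_span = 1)
  expect_identical(tr1$V_mem, tr2$V_mem)
  expect_identical(tr1$I_Na, tr2$I_Na)
})

test_that("trace CSV writer round-trips the sampled trajectory", {
  p <- config_A()
  tr <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 0.3),
                        t_span = 0.3, dt_out = 1e-3)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  d <- read_trace_csv(f)
  expect_equal(d$V_mem_V, tr$V_mem, tolerance = 1e-12)
  expect_equal(names(d), c("t_s", "V_mem_V", "V_gk_V", "I_in_A", "I_Na_A",
                           "I_K_A"))
  unlink(f)
})

test_that("tonic frequency is non-increasing in C_mem and in R_dk", {
  base <- config_A()
  rate_of <- function(p) {
    tr <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 3),
                          t_span = 3, dt_out = 2e-4)
    st <- detect_spikes(tr, 0.25)$spike_times
    coecn:::steady_rate(st, 3)
  }
  for (rdk in c(3.5e5, 4.7e5, 6e5)) {
    rates <- vapply(c(0.7e-6, 1e-6, 1.4e-6), function(cm) {
      p <- base; p$C_mem <- cm; p$R_dk <- rdk
      rate_of(p)
    }, 0.0)
    expect_true(all(diff(rates) <= 1e-6))
  }
  for (cm in c(0.7e-6, 1e-6, 1.4e-6)) {
    rates <- vapply(c(3.5e5, 4.7e5, 6e5), function(rdk) {
      p <- base; p$C_mem <- cm; p$R_dk <- rdk
      rate_of(p)
    }, 0.0)
    expect_true(all(diff(rates) <= 1e-6))
  }
})

test_that("sodium current spikes twice per cycle as the gate recrosses V_P", {
  p <- config_A()
  tr <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 1),
                        t_span = 1, dt_out = 5e-5)
  ## isolate one steady cycle between consecutive spikes
  st <- detect_spikes(tr, 0.25)$spike_times
  expect_gte(length(st), 3)
  sel <- tr$t >= st[2] - 0.02 & tr$t < st[3] - 0.02
  ina <- tr$I_Na[sel]
  ## two I_Na maxima per cycle (I_Na1 on the upstroke, I_Na2 on the
  ## downstroke as the gate recrosses V_P), separated by a dip at the
  ## voltage peak
  peaks <- which(diff(sign(diff(ina))) == -2) + 1
  peaks <- peaks[ina[peaks] > 0.3 * max(ina)]
  expect_gte(length(peaks), 2)
  ## amplifier output traverses V_P downwards and back within the cycle
  va <- amplifier_output(tr$V_mem[sel], p$amplifier)
  vp <- p$na_params$V_P0
  expect_lt(min(va), vp)
  expect_gt(max(va), vp)
})

test_that("halving solver tolerances moves spike times by < 0.1% of period", {
  p <- config_A()
  stim <- stimulus_program(baseline = 2e-6, t_max = 2)
  st1 <- detect_spikes(simulate_neuron(p, stim, t_span = 2, rtol = 1e-8,
                                       atol = 1e-10), 0.25)$spike_times
  st2 <- detect_spikes(simulate_neuron(p, stim, t_span = 2, rtol = 5e-9,
                                       atol = 5e-11), 0.25)$spike_times
  expect_equal(length(st1), length(st2))
  period <- mean(diff(st1))
  expect_lt(max(abs(st1 - st2)), 1e-3 * period)
})
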