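test_that("gaussian antiambipolar law matches closed-form reference values", {
  p <- antiambipolar_params(I_peak0 = 5e-6, V_P0 = 1.0,
                            sigma_rise = 0.15, sigma_fall = 0.15,
                            V_DS_ref = 0.3)
  ## at the peak position the current equals the peak current
  expect_equal(antiambipolar_current(1.0, 0.3, p), 5e-6)
  ## one sigma above the peak: I_peak * exp(-1/2)
  expect_equal(antiambipolar_current(1.15, 0.3, p), 5e-6 * exp(-0.5),
               tolerance = 1e-12)
  ## far tails are numerically zero
  expect_lt(antiambipolar_current(1.0 + 10 * 0.15, 0.3, p), 1e-20 * 5e-6)
  expect_lt(antiambipolar_current(1.0 - 10 * 0.15, 0.3, p), 1e-20 * 5e-6)
})

test_that("drain-bias dependence shifts peak, grows amplitude and width", {
  p <- antiambipolar_params(I_peak0 = 5e-6, V_P0 = 1.0, sigma_rise = 0.1,
                            sigma_fall = 0.1, V_DS_ref = 0.3,
                            k_peak = 1e-5, k_VP = 0.1, k_sigma = 0.5)
  vg <- seq(0, 2, by = 1e-3)
  lo <- antiambipolar_current(vg, 0.2, p)
  hi <- antiambipolar_current(vg, 0.5, p)
  expect_gt(max(hi), max(lo))                 # peak current grows
  expect_gt(vg[which.max(hi)], vg[which.max(lo)])  # V_P shifts up
  fwhm <- function(y) diff(range(vg[y > max(y) / 2]))
  expect_gt(fwhm(hi), fwhm(lo))               # FWHM broadens
  ## maximum is attained at V_P(V_DS)
  expect_equal(vg[which.max(hi)], p$V_P0 + p$k_VP * (0.5 - 0.3),
               tolerance = 2e-3)
})

test_that("gaussian law is unimodal and non-negative for varied parameters", {
  vg <- seq(-0.5, 2.5, by = 1e-3)
  cases <- expand.grid(sr = c(0.05, 0.15), sf = c(0.08, 0.2),
                       vds = c(0.1, 0.45))
  for (i in seq_len(nrow(cases))) {
    p <- antiambipolar_params(I_peak0 = 3e-6, V_P0 = 0.9,
                              sigma_rise = cases$sr[i],
                              sigma_fall = cases$sf[i],
                              V_DS_ref = 0.3, k_peak = 4e-6, k_sigma = 0.3)
    y <- antiambipolar_current(vg, cases$vds[i], p)
    expect_true(all(y >= 0))
    ds <- sign(diff(y))
    ds <- ds[ds != 0]
    expect_equal(sum(diff(ds) != 0), 1)  # exactly one sign change
  }
})

test_that("negative computed peak current is rejected", {
  p <- antiambipolar_params(I_peak0 = 1e-6, V_DS_ref = 0.5, k_peak = 1e-5)
  expect_error(antiambipolar_current(1, 0.0, p), "peak current")
})

test_that("two-species law reproduces threshold, non-monotonicity and limits", {
  p <- antiambipolar_params(V_Na_s = 0.4, mu_Na_s = 1e-4,
                            V_Na_m = 1.0, mu_Na_m = 1e-6, w_m = 0.08,
                            form = "two_species")
  ## below threshold: zero
  expect_equal(two_species_current(0.3, 0.3, p), 0)
  expect_equal(two_species_current(0.4, 0.3, p), 0)
  ## far above the conversion onset with mu_Na_m ~ 0 the current collapses
  p0 <- antiambipolar_params(V_Na_s = 0.4, mu_Na_s = 1e-4,
                             V_Na_m = 1.0, mu_Na_m = 1e-9, w_m = 0.05,
                             form = "two_species")
  vg <- seq(0, 3, by = 1e-3)
  y <- two_species_current(vg, 0.3, p0)
  expect_lt(y[length(y)], max(y) / 50)
  ## rises then falls: argmax strictly interior
  expect_gt(vg[which.max(y)], 0.5)
  expect_lt(vg[which.max(y)], 2.5)
})

test_that("two-species argmax and peak match a brute-force grid search", {
  p <- antiambipolar_params(V_Na_s = 0.4, mu_Na_s = 1e-4,
                            V_Na_m = 1.0, mu_Na_m = 1e-6, w_m = 0.08,
                            form = "two_species")
  ## independent oracle: dense evaluation of the defining formula
  vg <- seq(0, 3, by = 1e-5)
  mu <- p$mu_Na_s + (p$mu_Na_m - p$mu_Na_s) * plogis((vg - p$V_Na_m) / p$w_m)
  vov <- pmax(vg - p$V_Na_s, 0)
  veff <- pmin(0.3, vov)
  oracle <- mu * (vov * veff - veff^2 / 2)
  i <- which.max(oracle)
  ## frozen regression values from the oracle at the reference set
  expect_equal(vg[i], 0.90312, tolerance = 1e-4)
  expect_equal(oracle[i], 8.186428e-6, tolerance = 1e-4)
  expect_equal(two_species_current(vg[i], 0.3, p), oracle[i],
               tolerance = 1e-10)
})

test_that("two-species law collapses to the standard law without conversion", {
  p <- antiambipolar_params(V_Na_s = 0.35, mu_Na_s = 2e-4, V_Na_m = 1.2,
                            mu_Na_m = 2e-4, w_m = 0.1, form = "two_species")
  q <- oect_params(V_T = 0.35, K_g = 2e-4)
  vg <- seq(0, 2, by = 0.01)
  for (vds in c(0.1, 0.3, 0.8))
    expect_equal(two_species_current(vg, vds, p), oect_current(vg, vds, q),
                 tolerance = 1e-12)
})

test_that("standard OECT law reproduces regimes and monotonicity", {
  p <- oect_params(V_T = 0.2, K_g = 1e-3)
  expect_equal(oect_current(0.2, 0.5, p), 0)      # at threshold
  expect_equal(oect_current(0.1, 0.5, p), 0)      # below threshold
  expect_equal(oect_current(0.4, 1.0, p), 20e-6)  # saturation: K_g*0.2^2/2
  expect_equal(oect_current(0.4, 0.0, p), 0)      # zero drain bias
  ## linear regime value
  expect_equal(oect_current(0.5, 0.1, p), 1e-3 * (0.3 * 0.1 - 0.005))
  ## monotone in both arguments
  vgs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(oect_current(vgs, 0.3, p)) >= 0))
  vds <- seq(0, 1, by = 0.01)
  expect_true(all(diff(vapply(vds, function(v)
    oect_current(0.6, v, p), 0)) >= 0))
})

test_that("current laws are continuous across regime boundaries", {
  p <- oect_params(V_T = 0.2, K_g = 1e-3)
  ## across pinch-off (V_DS = V_GS - V_T) and threshold
  vgs <- seq(0.15, 0.7, by = 1e-5)
  y <- oect_current(vgs, 0.25, p)
  expect_lt(max(abs(diff(y))), 1e-8)
  pa <- antiambipolar_params(sigma_rise = 0.1, sigma_fall = 0.2)
  vg <- seq(0.5, 1.5, by = 1e-5)
  ya <- antiambipolar_current(vg, 0.3, pa)
  expect_lt(max(abs(diff(ya))), 1e-8)
})

test_that("inverting amplifier maps rest and peak voltages per calibration", {
  a <- amplifier_params()
  expect_equal(amplifier_output(0.175, a), 1.2, tolerance = 1e-3)
  expect_equal(amplifier_output(0.340, a), 0.8, tolerance = 1e-3)
  expect_equal(amplifier_output(10, a), a$rail_low)
  expect_equal(amplifier_output(-10, a), a$rail_high)
  v <- seq(0.1, 0.45, by = 0.01)
  expect_true(all(diff(amplifier_output(v, a)) < 0))  # strictly decreasing
})

test_that("antiambipolar fit recovers parameters from a synthetic table", {
  truth <- antiambipolar_params(I_peak0 = 8e-6, V_P0 = 0.95,
                                sigma_rise = 0.12, sigma_fall = 0.09,
                                V_DS_ref = 0.3)
  vg <- seq(0.3, 1.6, by = 0.02)
  d <- data.frame(V_G_V = vg, V_DS_V = 0.3,
                  I_D_A = antiambipolar_current(vg, 0.3, truth))
  fit <- fit_antiambipolar(d, V_DS_ref = 0.3)
  expect_equal(fit$I_peak0, truth$I_peak0, tolerance = 1e-3)
  expect_equal(fit$V_P0, truth$V_P0, tolerance = 1e-3)
  expect_equal(fit$sigma_rise, truth$sigma_rise, tolerance = 1e-2)
  expect_equal(fit$sigma_fall, truth$sigma_fall, tolerance = 1e-2)
})

test_that("transfer-curve CSV reader validates columns and round-trips", {
  d <- data.frame(V_G_V = c(0.5, 1), V_DS_V = 0.3, I_D_A = c(1e-6, 5e-6))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_equal(read_transfer_csv(f)$I_D_A, d$I_D_A)
  write.csv(d[, 1:2], f, row.names = FALSE)
  expect_error(read_transfer_csv(f), "missing columns")
  unlink(f)
})
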