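#' Antiambipolar Na-OECT parameter set
#'
#' Parameterizes the steady-state drain-current law of the antiambipolar
#' (Gaussian transfer curve) organic electrochemical transistor that plays
#' the role of the sodium channel. Two functional forms are supported:
#'
#' * `"gaussian"` — the phenomenological reference model. Drain current is a
#'   Gaussian in gate voltage whose peak current, peak position and widths
#'   depend (affinely) on the drain bias.
#' * `"two_species"` — a physically motivated alternative in which a standard
#'   transistor law with threshold `V_Na_s` and prefactor `mu_Na_s` crosses
#'   over, above an onset `V_Na_m`, to a reduced prefactor `mu_Na_m`,
#'   representing the conversion of singly charged to multiply charged
#'   (low-mobility) species at high electrochemical doping.
#'
#' All quantities are SI (volts, amperes).
#'
#' @param I_peak0 Peak drain current (A) at the reference drain bias.
#' @param V_P0 Gate voltage of the current peak (V) at the reference bias.
#' @param sigma_rise Gaussian width (V) on the low-gate-voltage side.
#' @param sigma_fall Gaussian width (V) on the high-gate-voltage side.
#' @param V_DS_ref Reference drain bias (V).
#' @param k_peak Peak-current sensitivity to drain bias (A/V).
#' @param k_VP Shift of the peak position per volt of drain bias
#'   (dimensionless).
#' @param k_sigma Fractional width growth per volt of drain bias (1/V).
#' @param V_Na_s Threshold voltage (V) of the singly-charged branch
#'   (two-species form).
#' @param mu_Na_s Prefactor (A/V^2) of the singly-charged branch.
#' @param V_Na_m Onset voltage (V) of multiply-charged conversion.
#' @param mu_Na_m Reduced prefactor (A/V^2) after conversion
#'   (`mu_Na_m < mu_Na_s`).
#' @param w_m Conversion width (V) of the logistic crossover.
#' @param form `"gaussian"` or `"two_species"`.
#'
#' @return An object of class `"aap_params"`.
#' @seealso [antiambipolar_current()], [two_species_current()]
#' @export
antiambipolar_params <- function(I_peak0 = 5e-6, V_P0 = 1.0,
                                 sigma_rise = 0.15, sigma_fall = 0.15,
                                 V_DS_ref = 0.3, k_peak = 0, k_VP = 0,
                                 k_sigma = 0,
                                 V_Na_s = 0.4, mu_Na_s = 1e-4,
                                 V_Na_m = 1.0, mu_Na_m = 1e-6, w_m = 0.1,
                                 form = c("gaussian", "two_species")) {
  form <- match.arg(form)
  stopifnot(I_peak0 > 0, sigma_rise > 0, sigma_fall > 0, V_DS_ref >= 0,
            w_m > 0)
  if (mu_Na_m > mu_Na_s)
    stop("mu_Na_m must not exceed mu_Na_s (reduced mobility after conversion)")
  if (V_Na_m <= V_Na_s)
    stop("V_Na_m must exceed V_Na_s")
  structure(list(I_peak0 = I_peak0, V_P0 = V_P0,
                 sigma_rise = sigma_rise, sigma_fall = sigma_fall,
                 V_DS_ref = V_DS_ref, k_peak = k_peak, k_VP = k_VP,
                 k_sigma = k_sigma,
                 V_Na_s = V_Na_s, mu_Na_s = mu_Na_s,
                 V_Na_m = V_Na_m, mu_Na_m = mu_Na_m, w_m = w_m,
                 form = form),
            class = "aap_params")
}

#' @export
print.aap_params <- function(x, ...) {
  cat("Antiambipolar OECT parameters (form:", x$form, ")\n")
  if (x$form == "gaussian") {
    cat(sprintf("  I_peak0 = %.3g A at V_DS_ref = %.3g V\n",
                x$I_peak0, x$V_DS_ref))
    cat(sprintf("  V_P0 = %.3g V, sigma (rise/fall) = %.3g/%.3g V\n",
                x$V_P0, x$sigma_rise, x$sigma_fall))
    cat(sprintf("  V_DS sensitivities: k_peak = %.3g A/V, k_VP = %.3g, k_sigma = %.3g /V\n",
                x$k_peak, x$k_VP, x$k_sigma))
  } else {
    cat(sprintf("  V_Na_s = %.3g V (mu = %.3g A/V^2), V_Na_m = %.3g V (mu = %.3g A/V^2), w_m = %.3g V\n",
                x$V_Na_s, x$mu_Na_s, x$V_Na_m, x$mu_Na_m, x$w_m))
  }
  invisible(x)
}

#' Steady-state drain current of the antiambipolar OECT (Gaussian form)
#'
#' Drain current as a function of gate voltage and drain bias for the
#' Gaussian (antiambipolar) transfer law:
#' \deqn{I(V_G, V_{DS}) = I_{peak}(V_{DS}) \exp\!\left(-\frac{(V_G - V_P(V_{DS}))^2}{2\sigma^2}\right)}
#' with \eqn{\sigma = \sigma_{rise}} below the peak and \eqn{\sigma_{fall}}
#' above it, and affine drain-bias dependence
#' \eqn{I_{peak} = I_{peak0} + k_{peak}(V_{DS} - V_{DS,ref})},
#' \eqn{V_P = V_{P0} + k_{VP}(V_{DS} - V_{DS,ref})}, widths scaled by
#' \eqn{1 + k_\sigma (V_{DS} - V_{DS,ref})}. Higher drain bias thus raises the
#' peak current, shifts the peak position and broadens the curve.
#'
#' @param V_G Gate voltage(s), V. Vectorized (recycled against `V_DS`).
#' @param V_DS Drain bias(es), V (`>= 0`). Vectorized.
#' @param p An [antiambipolar_params()] object.
#' @return Drain current(s) in amperes (non-negative).
#' @export
antiambipolar_current <- function(V_G, V_DS, p) {
  stopifnot(inherits(p, "aap_params"), all(V_DS >= 0))
  dv <- V_DS - p$V_DS_ref
  I_pk <- p$I_peak0 + p$k_peak * dv
  if (any(I_pk < -1e-9 * p$I_peak0))
    stop("computed peak current is negative: V_DS = ",
         V_DS[which(I_pk < -1e-9 * p$I_peak0)[1]],
         " is outside the parameter domain")
  I_pk <- pmax(I_pk, 0)  # guard rounding at the zero-bias endpoint
  V_P <- p$V_P0 + p$k_VP * dv
  wscale <- 1 + p$k_sigma * dv
  if (any(wscale <= 0))
    stop("computed Gaussian width is non-positive at V_DS = ",
         V_DS[which(wscale <= 0)[1]])
  sig <- ifelse(V_G < V_P, p$sigma_rise, p$sigma_fall) * wscale
  I_pk * exp(-(V_G - V_P)^2 / (2 * sig^2))
}

## standard transistor drain factor: linear below pinch-off, saturated
## above; unified as V_ov*V_eff - V_eff^2/2 with V_eff = min(V_DS, V_ov).
## Vectorized in both arguments.
drain_factor <- function(V_ov, V_DS) {
  V_ov <- pmax(V_ov, 0)
  V_eff <- pmin(V_DS, V_ov)
  V_ov * V_eff - V_eff^2 / 2
}

#' Steady-state drain current of the antiambipolar OECT (two-species form)
#'
#' Alternative antiambipolar law built from the standard transistor drain
#' factor with a gate-voltage-dependent effective prefactor
#' \deqn{\mu_{eff}(V_G) = \mu_{Na\text{-}s} + (\mu_{Na\text{-}m} - \mu_{Na\text{-}s})\,
#'   \mathrm{logistic}\!\left(\frac{V_G - V_{Na\text{-}m}}{w_m}\right)}
#' so that the current rises above the threshold `V_Na_s` (singly charged
#' species) and falls again once multiply charged, low-mobility species
#' dominate above `V_Na_m` — reproducing the non-monotone transfer curve.
#'
#' @inheritParams antiambipolar_current
#' @return Drain current(s) in amperes (non-negative).
#' @export
two_species_current <- function(V_G, V_DS, p) {
  stopifnot(inherits(p, "aap_params"), V_DS >= 0)
  if (p$form != "two_species")
    stop("two_species_current requires params with form = 'two_species'")
  mu_eff <- p$mu_Na_s + (p$mu_Na_m - p$mu_Na_s) *
    stats::plogis((V_G - p$V_Na_m) / p$w_m)
  mu_eff * drain_factor(V_G - p$V_Na_s, V_DS)
}

#' Standard OECT parameter set (K-OECT)
#'
#' Monotone transistor law used for the potassium-branch OECT: threshold
#' voltage `V_T` (the potassium threshold V_K) and transconductance prefactor
#' `K_g` = W d mu C*/L. The potassium device uses the thicker-film,
#' higher-current parameterization. `C_g` and `R_g_intrinsic` give the
#' intrinsic gate RC that limits switching speed.
#'
#' @param V_T Threshold voltage (V).
#' @param K_g Transconductance prefactor (A/V^2), `> 0`.
#' @param C_g Intrinsic gate capacitance (F), `> 0`.
#' @param R_g_intrinsic Intrinsic gate resistance (Ohm).
#' @return An object of class `"oect_params"`.
#' @export
oect_params <- function(V_T = 0.2, K_g = 1e-3, C_g = 1e-7,
                        R_g_intrinsic = 2.5e3) {
  stopifnot(K_g > 0, C_g > 0, R_g_intrinsic > 0)
  structure(list(V_T = V_T, K_g = K_g, C_g = C_g,
                 R_g_intrinsic = R_g_intrinsic),
            class = "oect_params")
}

#' @export
print.oect_params <- function(x, ...) {
  cat(sprintf("OECT parameters: V_T = %.3g V, K_g = %.3g A/V^2, gate RC = %.3g s\n",
              x$V_T, x$K_g, x$C_g * x$R_g_intrinsic))
  invisible(x)
}

#' Steady-state drain current of a standard (monotone) OECT
#'
#' Quadratic transistor law: zero below threshold,
#' `K_g * ((V_GS - V_T) * V_DS - V_DS^2/2)` in the linear regime and
#' `K_g * (V_GS - V_T)^2 / 2` in saturation. Continuous and monotone
#' non-decreasing in both arguments.
#'
#' @param V_GS Gate-source voltage(s), V. Vectorized (recycled against
#'   `V_DS`).
#' @param V_DS Drain-source bias(es), V (`>= 0`). Vectorized.
#' @param p An [oect_params()] object.
#' @return Drain current(s) in amperes.
#' @export
oect_current <- function(V_GS, V_DS, p) {
  stopifnot(inherits(p, "oect_params"), all(V_DS >= 0))
  p$K_g * drain_factor(V_GS - p$V_T, V_DS)
}

#' Inverting-amplifier parameter set
#'
#' Saturating linear map from the membrane voltage to the Na-OECT gate:
#' `clamp(gain * V_in + offset, rail_low, rail_high)`, with negative gain.
#' The reference calibration maps the 175 mV resting membrane voltage to a
#' 1.2 V gate voltage and the 340 mV depolarization peak to 0.8 V, so one
#' spike sweeps the Na-OECT gate across the antiambipolar peak and back.
#'
#' @param gain Dimensionless slope (`< 0`).
#' @param offset Output offset (V).
#' @param rail_low,rail_high Output saturation rails (V).
#' @return An object of class `"amp_params"`.
#' @export
amplifier_params <- function(gain = -2.424242, offset = 1.624242,
                             rail_low = 0.5, rail_high = 1.4) {
  stopifnot(gain < 0, rail_low < rail_high)
  structure(list(gain = gain, offset = offset,
                 rail_low = rail_low, rail_high = rail_high),
            class = "amp_params")
}

#' @export
print.amp_params <- function(x, ...) {
  cat(sprintf("Inverting amplifier: gain = %.4g, offset = %.4g V, rails [%.3g, %.3g] V\n",
              x$gain, x$offset, x$rail_low, x$rail_high))
  invisible(x)
}

#' Inverting-amplifier output voltage
#'
#' @param V_in Input voltage(s), V. Vectorized.
#' @param p An [amplifier_params()] object.
#' @return Output voltage(s), V, clamped to the rails.
#' @export
amplifier_output <- function(V_in, p) {
  stopifnot(inherits(p, "amp_params"))
  pmin(pmax(p$gain * V_in + p$offset, p$rail_low), p$rail_high)
}

#' Step-response switching time of an OECT
#'
#' Applies a gate-voltage step from `V_from` to `V_to` through the device's
#' intrinsic gate RC (`R_g_intrinsic * C_g`) at fixed drain bias, evaluates
#' the static current law along the first-order gate lag
#' `V_GS(t) = V_to + (V_from - V_to) exp(-t / RC)`, and reports the
#' 10-90% rise time of the drain current (linear interpolation on a fine
#' grid). OECT switching is limited by this ionic gate RC; the reference
#' potassium-device parameterization switches in well under a millisecond.
#'
#' @param p An [oect_params()] object.
#' @param V_from Initial gate voltage (V); defaults to below threshold.
#' @param V_to Final gate voltage (V); defaults to `V_T + 0.3`.
#' @param V_DS Drain bias (V).
#' @param dt Evaluation grid spacing (s).
#' @return List with `rise_time_s` (10-90%), `t10_s`, `t90_s` and the
#'   evaluated `t`, `I` arrays.
#' @export
oect_switching_time <- function(p, V_from = p$V_T - 0.1,
                                V_to = p$V_T + 0.3, V_DS = 0.3,
                                dt = 1e-7) {
  stopifnot(inherits(p, "oect_params"), V_to > V_from)
  tau <- p$R_g_intrinsic * p$C_g
  t <- seq(0, 10 * tau, by = dt)
  vgs <- V_to + (V_from - V_to) * exp(-t / tau)
  I <- oect_current(vgs, V_DS, p)
  I_inf <- oect_current(V_to, V_DS, p)
  cross <- function(level) {
    i <- which(I >= level)[1]
    if (i == 1) return(t[1])
    t[i - 1] + (level - I[i - 1]) / (I[i] - I[i - 1]) * dt
  }
  t10 <- cross(0.1 * I_inf)
  t90 <- cross(0.9 * I_inf)
  list(rise_time_s = t90 - t10, t10_s = t10, t90_s = t90, t = t, I = I)
}

#' Read a measured transfer-curve table
#'
#' Reads a CSV with columns `V_G_V`, `V_DS_V`, `I_D_A` (gate voltage, drain
#' bias and drain current, SI units), as produced by parameter analysers or
#' by [antiambipolar_current()] itself.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with the three columns, checked and coerced numeric.
#' @export
read_transfer_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("V_G_V", "V_DS_V", "I_D_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("transfer-curve CSV is missing columns: ", paste(miss, collapse = ", "))
  d[need] <- lapply(d[need], as.numeric)
  d
}

#' Fit Gaussian antiambipolar parameters to a transfer-curve table
#'
#' Least-squares fit of the Gaussian antiambipolar law (including its affine
#' drain-bias dependence when the table contains more than one drain bias)
#' to measured (V_G, V_DS, I_D) triples. Uses `stats::optim` (BFGS on
#' log-width / log-peak scales) from moment-based starting values.
#'
#' @param data A data.frame as returned by [read_transfer_csv()].
#' @param V_DS_ref Reference drain bias for the fitted parameter set;
#'   defaults to the median drain bias in the table.
#' @return An [antiambipolar_params()] object with fitted values and the
#'   residual sum of squares in attribute `"rss"`.
#' @export
fit_antiambipolar <- function(data, V_DS_ref = stats::median(data$V_DS_V)) {
  stopifnot(all(c("V_G_V", "V_DS_V", "I_D_A") %in% names(data)))
  multi_vds <- length(unique(data$V_DS_V)) > 1
  ipk0 <- max(data$I_D_A)
  vp0 <- data$V_G_V[which.max(data$I_D_A)]
  ## per-side width starts from the half-maximum distances
  half <- ipk0 / 2
  lo <- data$V_G_V[data$V_G_V < vp0 & data$I_D_A >= half]
  hi <- data$V_G_V[data$V_G_V > vp0 & data$I_D_A >= half]
  hwhm <- sqrt(2 * log(2))
  s_lo <- if (length(lo)) max((vp0 - min(lo)) / hwhm, 0.01) else 0.05
  s_hi <- if (length(hi)) max((max(hi) - vp0) / hwhm, 0.01) else 0.05
  theta0 <- c(log(ipk0), vp0, log(s_lo), log(s_hi),
              if (multi_vds) c(0, 0, 0) else NULL)
  model <- function(th) {
    kp <- if (multi_vds) th[5] else 0
    kv <- if (multi_vds) th[6] else 0
    ks <- if (multi_vds) th[7] else 0
    dv <- data$V_DS_V - V_DS_ref
    ipk <- exp(th[1]) * (1 + kp * dv)
    vp <- th[2] + kv * dv
    w <- pmax(1 + ks * dv, 1e-6)
    sig <- ifelse(data$V_G_V < vp, exp(th[3]), exp(th[4])) * w
    ipk * exp(-(data$V_G_V - vp)^2 / (2 * sig^2))
  }
  obj <- function(th) sum((model(th) - data$I_D_A)^2)
  ## Nelder-Mead handles the kink at V_P; BFGS then polishes
  fit <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  th <- fit$par
  out <- antiambipolar_params(
    I_peak0 = exp(th[1]), V_P0 = th[2],
    sigma_rise = exp(th[3]), sigma_fall = exp(th[4]),
    V_DS_ref = V_DS_ref,
    k_peak = if (multi_vds) exp(th[1]) * th[5] else 0,
    k_VP = if (multi_vds) th[6] else 0,
    k_sigma = if (multi_vds) th[7] else 0)
  attr(out, "rss") <- fit$value
  out
}
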