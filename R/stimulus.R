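#' Build a stimulus program
#'
#' A stimulus program is a baseline current plus an ordered list of
#' non-overlapping segments (constant pulses or linear ramps) and optional
#' seeded noise. Evaluation is a pure function of the program and time: the
#' noise path is generated once on a fixed internal grid (`noise_dt`,
#' default 0.1 ms) from the seed, by exact discretization for the
#' Ornstein-Uhlenbeck model, and linearly interpolated — so the stimulus is
#' independent of the ODE solver's step sequence.
#'
#' @param segments A list of segments; each is a list with fields
#'   `t_start` (s), `duration` (s), `kind` (`"constant"` or `"ramp"`) and
#'   either `amplitude` (A) or `start`/`end` amplitudes (A) for a ramp.
#'   Segment amplitudes are added to the baseline while active.
#' @param baseline Baseline current (A).
#' @param noise `NULL`, or a list with fields `model` (`"white"` or `"OU"`),
#'   `sigma` (A, standard deviation), `tau` (s, OU correlation time) and
#'   `seed` (integer).
#' @param t_max Time horizon (s) over which a noise path is pre-generated.
#' @param noise_dt Internal noise grid spacing (s).
#' @return An object of class `"stimulus_program"`.
#' @export
stimulus_program <- function(segments = list(), baseline = 0, noise = NULL,
                             t_max = 10, noise_dt = 1e-4) {
  segments <- lapply(segments, function(s) {
    stopifnot(s$t_start >= 0, s$duration > 0,
              s$kind %in% c("constant", "ramp"))
    if (s$kind == "constant") stopifnot(is.numeric(s$amplitude))
    else stopifnot(is.numeric(s$start), is.numeric(s$end))
    s
  })
  if (length(segments) > 1) {
    o <- order(vapply(segments, `[[`, 0, "t_start"))
    segments <- segments[o]
    ends <- vapply(segments, function(s) s$t_start + s$duration, 0)
    starts <- vapply(segments, `[[`, 0, "t_start")
    if (any(starts[-1] < ends[-length(ends)] - 1e-12))
      stop("stimulus segments overlap")
  }
  noise_path <- NULL
  if (!is.null(noise)) {
    stopifnot(noise$model %in% c("white", "OU"), noise$sigma >= 0)
    if (is.null(noise$seed)) noise$seed <- 1L
    if (noise$model == "OU" && is.null(noise$tau)) noise$tau <- 0.01
    noise_path <- make_noise_path(noise, t_max, noise_dt)
  }
  structure(list(segments = segments, baseline = baseline, noise = noise,
                 noise_path = noise_path, t_max = t_max,
                 noise_dt = noise_dt),
            class = "stimulus_program")
}

## Pre-generate a noise path on the fixed grid. OU uses the exact AR(1)
## discretization x_{k+1} = a x_k + sigma*sqrt(1-a^2) z_k with
## a = exp(-dt/tau); "white" is i.i.d. N(0, sigma^2) per grid point.
make_noise_path <- function(noise, t_max, dt) {
  tg <- seq(0, t_max + dt, by = dt)
  n <- length(tg)
  if (noise$sigma == 0) return(list(t = tg, x = numeric(n)))
  rng <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(noise$seed)
    z <- stats::rnorm(n)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    z
  })
  if (noise$model == "white") {
    x <- noise$sigma * rng
  } else {
    a <- exp(-dt / noise$tau)
    s <- noise$sigma * sqrt(1 - a^2)
    x <- as.numeric(stats::filter(c(noise$sigma * rng[1], s * rng[-1]),
                                  a, method = "recursive"))
  }
  list(t = tg, x = x)
}

#' Evaluate a stimulus program
#'
#' @param stim A [stimulus_program()].
#' @param t Time(s) in seconds, `>= 0`. Vectorized.
#' @return Current(s) in amperes.
#' @export
evaluate_stimulus <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus_program"), all(t >= 0))
  out <- rep(stim$baseline, length(t))
  for (s in stim$segments) {
    act <- t >= s$t_start & t < s$t_start + s$duration
    if (!any(act)) next
    if (s$kind == "constant") {
      out[act] <- out[act] + s$amplitude
    } else {
      frac <- (t[act] - s$t_start) / s$duration
      out[act] <- out[act] + s$start + (s$end - s$start) * frac
    }
  }
  if (!is.null(stim$noise_path) && stim$noise$sigma > 0) {
    np <- stim$noise_path
    tt <- pmin(t, np$t[length(np$t)])
    out <- out + stats::approx(np$t, np$x, xout = tt, rule = 2)$y
  }
  out
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat(sprintf("Stimulus program: baseline %.3g A, %d segment(s)",
              x$baseline, length(x$segments)))
  if (!is.null(x$noise))
    cat(sprintf(", %s noise sigma = %.3g A (seed %d)",
                x$noise$model, x$noise$sigma, x$noise$seed))
  cat("\n")
  for (s in x$segments) {
    if (s$kind == "constant")
      cat(sprintf("  [%.4g, %.4g] s: constant %+.3g A\n",
                  s$t_start, s$t_start + s$duration, s$amplitude))
    else
      cat(sprintf("  [%.4g, %.4g] s: ramp %+.3g -> %+.3g A\n",
                  s$t_start, s$t_start + s$duration, s$start, s$end))
  }
  invisible(x)
}

seg_const <- function(t_start, duration, amplitude)
  list(t_start = t_start, duration = duration, kind = "constant",
       amplitude = amplitude)

seg_ramp <- function(t_start, duration, start, end)
  list(t_start = t_start, duration = duration, kind = "ramp",
       start = start, end = end)

#' Library of standard stimulation protocols
#'
#' Parameterized stimulus templates for the neurocomputational feature
#' battery. Available protocols:
#'
#' * `"step"` — constant step of `amplitude` from `t_on` to the horizon
#'   (rheobase search, tonic spiking, onset/phasic analysis).
#' * `"paired_pulse"` — two identical pulses of `amplitude` and `width`
#'   separated by gap `delta` (integration when subthreshold,
#'   refractoriness/resonance when suprathreshold).
#' * `"neg_then_test"` — a negative conditioning pulse followed by a test
#'   pulse (threshold variability).
#' * `"neg_release"` — a long negative pulse whose release may trigger a
#'   rebound spike.
#' * `"ramp_vs_step"` — returns a list of two programs reaching the same
#'   final amplitude, a slow ramp and a step (accommodation).
#'
#' @param name Protocol name (see above).
#' @param amplitude Pulse/step amplitude (A).
#' @param width Pulse width (s).
#' @param delta Gap between paired pulses (s).
#' @param t_on Onset time (s).
#' @param t_max Program horizon (s).
#' @param baseline Baseline current (A).
#' @param neg_amplitude Amplitude of the negative conditioning pulse (A, < 0).
#' @param ramp_duration Duration of the slow ramp (s).
#' @return A [stimulus_program()], or a named list of two for
#'   `"ramp_vs_step"`.
#' @export
protocol_library <- function(name, amplitude = 2e-6, width = 0.05,
                             delta = 0.02, t_on = 0.5, t_max = 5,
                             baseline = 0, neg_amplitude = -2e-6,
                             ramp_duration = 2) {
  switch(name,
    step = stimulus_program(
      list(seg_const(t_on, t_max - t_on, amplitude)),
      baseline = baseline, t_max = t_max),
    paired_pulse = stimulus_program(
      list(seg_const(t_on, width, amplitude),
           seg_const(t_on + width + delta, width, amplitude)),
      baseline = baseline, t_max = t_max),
    neg_then_test = stimulus_program(
      list(seg_const(t_on, width, neg_amplitude),
           seg_const(t_on + width + delta, width, amplitude)),
      baseline = baseline, t_max = t_max),
    neg_release = stimulus_program(
      list(seg_const(t_on, width, neg_amplitude)),
      baseline = baseline, t_max = t_max),
    ramp_vs_step = list(
      ramp = stimulus_program(
        list(seg_ramp(t_on, ramp_duration, 0, amplitude),
             seg_const(t_on + ramp_duration, t_max - t_on - ramp_duration,
                       amplitude)),
        baseline = baseline, t_max = t_max),
      step = stimulus_program(
        list(seg_const(t_on + ramp_duration,
                       t_max - t_on - ramp_duration, amplitude)),
        baseline = baseline, t_max = t_max)),
    stop("unknown protocol: ", name)
  )
}
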