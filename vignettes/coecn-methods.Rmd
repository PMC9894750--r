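---
title: "Modelling conductance-based organic electrochemical neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conductance-based organic electrochemical neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coecn)
```

## The circuit model

A conductance-based organic electrochemical neuron (c-OECN) couples two
OECTs to two supply voltages, mirroring the sodium and potassium branches
of the Hodgkin–Huxley equivalent circuit. The package integrates the
two-node system

$$(C_{mem}+C_{int})\,\dot V_{mem} = I_{in}(t) + I_{Na} - I_K - G_L\,(V_{mem}-E_L),
\qquad \dot V_{gk} = \frac{V_{mem}-V_{gk}}{R_{dk} C_{gK}},$$

where the sodium current is the antiambipolar OECT law evaluated at the
inverting-amplifier output,

$$I_{Na} = I_{peak}(V_{DS})\,
  \exp\!\left(-\frac{(V_G - V_P(V_{DS}))^2}{2\sigma^2(V_{DS})}\right),
\qquad V_G = \mathrm{clamp}(g\,V_{mem}+b,\ \text{rails}),
\qquad V_{DS} = \max(E_{Na}-V_{mem},0),$$

and the potassium current is a standard quadratic transistor law at
gate-source voltage $V_{gk}-E_K$ and drain bias $V_{mem}-E_K$. The
delayed gate node $V_{gk}$ (a first-order lag of $V_{mem}$ with time
constant $R_{dk} C_{gK}$) is the single recovery variable: it is what makes
the potassium branch turn on *after* the sodium surge, exactly as the
delayed-rectifier conductance does in biology. Dynamically the system is a
relaxation oscillator of FitzHugh–Nagumo type: the Gaussian bump in
$I_{Na}(V_{mem})$ supplies the regenerative (N-shaped) fast nullcline and
$V_{gk}$ the slow negative feedback.

Two functional forms are provided for the antiambipolar branch. The
Gaussian form above is the reference model, motivated by the measured
Gaussian-shaped transfer curves of ladder-polymer OECTs; its drain-bias
dependence (peak current, peak position, width) is affine around a
reference bias because measurements show monotone growth and broadening
without suggesting a specific law. The `two_species` form derives the
non-monotonicity physically: a standard transistor law whose prefactor
crosses over, above an onset voltage, from the mobility of singly charged
to that of multiply charged (nearly immobile) species. The exact analytic
form used in the original SPICE models is not public; both forms are
therefore declared stand-ins fitted to the same phenomenology, and `form`
is a configuration switch defaulting to Gaussian.

The amplifier is a saturating linear map with negative gain. Its reference
calibration (gain $-2.42$, offset $1.624$ V, rails $[0.5, 1.4]$ V) maps the
175 mV resting membrane voltage to a 1.2 V gate voltage and the 0.34 V
depolarization peak to 0.8 V, so each spike sweeps the Na-OECT gate down
through the current peak $V_P$ and back, producing the characteristic
double sodium surge ($I_{Na1}$ on the upstroke, $I_{Na2}$ on the
downstroke).

A small explicit leak ($G_L$, $E_L$) fixes the resting point. The device
literature leaves open whether the physical circuit relies on an explicit
leak or on device off-currents; an explicit leak is the cleanest way to
obtain a well-defined, stable 175 mV rest, and $E_L$ is calibrated to place
the rest exactly there.

## Reference calibrations

Every shipped configuration (`config_A`, `config_B`, `config_C`, the
sensing configurations, and the modulator coefficients in
`reference_coefficients`) is a **calibration**: device constants chosen
once so that the simulated circuit reproduces its documented operating
points, not measured device parameters. The three circuit configurations
share one device table and differ only in the external capacitor, the
delay resistor and (for C) the amplifier stage:

* **A** — $C_{mem} = 1\,\mu F$, $R_{dk} = 470\,k\Omega$: rest 175 mV,
  5.0 Hz tonic spiking at 2 µA, peak 0.345 V, undershoot below rest.
* **B** — no external capacitor, $R_{dk} = 46.0\,k\Omega$: the same
  waveform ~16× faster (80 Hz), the reference for the energy bookkeeping.
* **C** — B with the OECT-amplifier parameterization (gain $-2.6$,
  rails $[0.55, 1.38]$ V) and a retuned intrinsic capacitance: 100 Hz.

The calibration order was: (i) device table and $E_L$ to put the rest at
175 mV with both Jacobian eigenvalues negative; (ii) $C_{gK}$ bisected so A
spikes at 5.000 Hz; (iii) $V_T$ placed so the $E_K$ class sequence (below)
switches at the documented values; (iv) $R_{dk}$ of B and C bisected to 80
and 100 Hz; (v) $C_{int}$ and the power-bookkeeping gate capacitance
$C_{g,Na}$ solved jointly so B's steady period integrates to 175 nJ per
spike with a 60 µW peak. These constants are frozen in `R/configs.R` and
never adjusted at run time.

## Excitability classes and their mechanism

Lowering $E_K$ makes the K-OECT turn on earlier in the cycle. In the model
this moves the depolarized fixed point of the fast subsystem down the
rising flank of the sodium bump, reducing the regenerative slope until the
fixed point stabilises (a subcritical Hopf scenario). The observable
sequence at 2 µA is: tonic class 1 at $E_K = -50$ mV, class 2 at
$-65$ mV, a two-spike onset burst (phasic bursting) at $-70$ mV and a
single onset spike (phasic spiking) at $-72$ mV. Routing Ca²⁺ to the
K-OECT electrolyte shifts $V_K$ by `dVK_coeff` × concentration
(−10 mV/mM by calibration) and reproduces the same sequence, since only
$V_{gk} - E_K - V_K$ enters the turn-on condition.

`classify_excitability` uses three named constants, all configurable:
`T_onset` = 300 ms (all spikes of a ≥3 s step inside this window ⇒
class 3, subdivided by onset spike count), `f_jump` = 60 % (smallest
nonzero f–I rate above this fraction of the top-of-grid rate ⇒ class 2,
i.e. an abrupt finite-frequency onset), otherwise class 1. The f–I grid
(`standard_I_grid`) spans the 0.5–6 µA operating range quasi-
logarithmically with a point near the class-1 rheobase so that the graded
onset is resolved; class-2 detection is deliberately a *ratio* criterion so
it does not depend on absolute rate calibration.

## Electrolyte modulation

Ion species shift the antiambipolar peak log-linearly,
$\Delta V_P = -(s/z)\log_{10}(c/c_{ref})$, a Nernst-like form with the
default slope 0.059 V/decade divided by valence; slopes are per-species
configuration values because the quantitative shifts are known only
graphically. Modulator molecules act linearly in concentration on $V_P$
and $V_K$ and attenuate $I_{peak}$ multiplicatively with saturation at
full suppression. Acetylcholine carries all-zero coefficients (it does
not shift the transfer curve); GABA and glutamine carry negative $V_P$
coefficients plus attenuation. The glutamine reference coefficients
(−22.8 mV/mM, 17.1 %/mM) are calibrated so tonic spiking of configuration
A ceases at 1.0 mM on a 0.1 mM grid.

Because the amplifier inverts, *lowering* $V_P$ moves the excitable region
*away* from rest: negative-coefficient modulators suppress spiking, which
is the GABA/glutamine inhibition mechanism. The NaCl sensing calibration
therefore uses a negative concentration slope (−0.1 V/decade) together
with a retuned $V_P$, so that low Na⁺ leaves the peak below the excitable
band and the neuron silent, while ≥50 mM restores spiking — the
spike-only-above-25 mM panel. The directional sign of the concentration
shift is a free calibration here, as the underlying measurements constrain
magnitude better than sign. The low-glutamine window (spiking only below
900 µM) uses the same chemistry with a slightly lowered $V_P$ baseline;
the high-glutamine window (spiking only above 1.8 mM) starts with the
peak *above* the resting gate voltage — the neuron sits in a quiescent
depolarized state — until the glutamine-induced shift pulls the peak back
into the excitable band.

Concentrations are piecewise-constant per simulation segment; there is no
diffusion, depletion or time-dependent electrolyte dynamics.

## Bistability, GABA wash-out and stochastic skipping

At 2 µA the reference neuron is *bistable*: a stable depolarized focus
(V ≈ 0.22 V, eigenvalues −3.8 ± 31.6i s⁻¹) coexists with the spiking limit
cycle. Two package behaviours follow directly:

* **GABA reversibility.** The GABA-inhibited operating point lies inside
  the quiescent basin of the restored circuit, so a noiseless continuation
  after wash-out stays silent. `run_gaba_inhibition` therefore adds a
  small seeded Ornstein–Uhlenbeck current (default σ = 0.3 µA) to the
  wash-out segment; the kick returns the state to the limit cycle and the
  run remains bit-reproducible.
* **Spike skipping.** `run_skipping_ensemble` drives the class-2 neuron
  ($E_K = -65$ mV) just above rheobase (1.8 µA), where low noise leaves
  dense tonic firing while stronger noise intermittently captures the
  trajectory in the quiescent focus for an integer number of subthreshold
  ringing periods (the focus frequency, 32.6 rad/s ≈ 5 Hz, matches the
  cycle period). Interspike intervals therefore cluster at integer
  multiples of the base period: the skip fraction grows with noise
  amplitude while the base frequency stays within a few percent. The
  noise spectrum of the original experiments is not stated; OU noise with
  τ = 10 ms is used because the circuit's millisecond-scale dynamics make
  band-limited noise the physically sensible stand-in, generated by exact
  discretization on a fixed 0.1 ms grid so the stimulus is independent of
  solver adaptivity.

`skipping_statistics` estimates the base period as the mode of the pooled
ISI density and assigns each ISI its nearest integer multiple within a 25 %
tolerance; the skip fraction is the share with multiple ≥ 2.

## Energy bookkeeping

Instantaneous supply power is defined as
$P(t) = |E_{Na} I_{Na}| + |E_K I_K| + V_{rail}\,C_{g,Na}\,|\dot V_G|$ —
the two branch supplies plus the amplifier output stage modelled as the
Na-OECT gate-charging current delivered from the high rail. Energy per
spike is the trapezoidal integral of $P$ over one steady period (between
the last two detected spikes). The published figures do not define their
power bookkeeping; this definition is the package's own and the
$C_{g,Na}$ constant is part of the calibration that reproduces the
175 nJ / 60 µW budget at 80 Hz.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`;
  the Gaussian nonlinearity plus millisecond gate lags make the system
  moderately stiff, and lsoda switches to BDF where needed. A fixed-step
  RK4 path is available for bit-reproducible regression fixtures. The
  maximum step is capped (1 ms, tighter when short stimulus segments are
  present) so pulses are never stepped over. Halving the tolerances moves
  spike times of the reference run by well under 0.1 % of the period.
* **Solver right-hand side.** The integrator uses an inlined scalar
  implementation of the device laws; the exported `circuit_rhs` is the
  reference version and the test suite asserts the two agree along
  trajectories (KCL residual at machine precision).
* **Resting state.** Damped Newton from $E_L$ on the 1-D quiescent
  problem ($V_{gk} = V_{mem}$), verified stable via the eigenvalues of the
  2×2 Jacobian; if Newton stalls or lands on an unstable root, a
  bracketing grid scan over the operating band finds a stable root.
* **Spike detection.** Upward threshold crossings at 0.25 V (midway
  between rest and peak) with linear interpolation between samples;
  steady rates discard the first 20 % of the window.
* **Determinism.** All randomness enters through stimulus seeds; noise
  paths are pre-generated from the seed (restoring the global RNG state),
  so identical configuration + seed gives bit-identical traces.
* **Problem sizes.** Tonic rates are measured on 5 s (configuration A) or
  2 s (B, C) runs at 0.1 ms output sampling (10 µs for energy integrals);
  sensing scans use 3 s windows with a ≥3-spike criterion; the skipping
  ensemble uses 21 seeded 5 s runs. These sizes give rate estimates well
  inside the tolerances quoted above.

## What the simulations do and do not show

The generator of all inputs is the package itself: stimulus programs,
electrolytes and device laws are idealized, noise is stationary OU, and
device constants are desk calibrations to printed operating points. Real
devices add drift, hysteresis between forward and reverse sweeps
(`sigma_rise`/`sigma_fall` asymmetry is supported but the defaults differ
only mildly), electrode impedances, temperature effects and
cycle-to-cycle variability — none of which are modelled. Passing tests
therefore demonstrate that the *model class* reproduces the documented
circuit behaviours under the shipped calibrations, not that a particular
physical device will. The in vivo nerve-stimulation results associated
with this class of devices are outside the package's scope entirely.

Known limitations: no transistor-level amplifier model (a saturating
linear map stands in), no electrochemical impedance or doping kinetics,
no p-type device models, and the feature battery's resonance and
threshold-variability detectors are sensitive to protocol parameters on
configurations tuned differently from the reference one.
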