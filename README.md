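# coecn

Desk-scale circuit simulation of **conductance-based organic
electrochemical neurons** (c-OECNs): spiking circuits built from two
organic electrochemical transistors (OECTs) whose channel conductances play
the roles of the sodium and potassium conductances of the Hodgkin–Huxley
model. The package is aimed at researchers in organic neuromorphics and
bioelectronics who want to explore, before fabrication, how device-level
parameters (transfer-curve shape, thresholds, gate RC), circuit elements
(membrane capacitor, delay resistor, supply voltages) and electrolyte
composition (ions, neurotransmitters, amino acids) shape neural behaviour.

## The model

The sodium branch is an **antiambipolar** OECT: its drain current rises and
then falls with gate voltage, giving a Gaussian-shaped transfer curve

> I(V_G, V_DS) = I_peak(V_DS) · exp( −(V_G − V_P(V_DS))² / 2σ(V_DS)² )

whose two flanks emulate the activation and inactivation of the biological
sodium channel. The potassium branch is a standard monotone OECT
(quadratic law with threshold V_K), and an inverting amplifier maps the
membrane voltage onto the Na-OECT gate so that one spike sweeps the gate
across the current peak and back. The circuit has two state variables:

> (C_mem + C_int) · dV_mem/dt = I_in(t) + I_Na − I_K − G_L (V_mem − E_L)
>
> dV_gk/dt = (V_mem − V_gk) / (R_dk · C_gK)

with I_Na evaluated at gate voltage `amplifier(V_mem)` and drain bias
`E_Na − V_mem`, and I_K at gate-source voltage `V_gk − E_K` and drain bias
`V_mem − E_K`. The delayed gate node V_gk is what gives the potassium
branch its biological "delayed rectifier" character. Electrolyte
composition enters through shifts of V_P (log-linear in ion concentration,
linear in modulator concentration), attenuation of I_peak, and shifts of
V_K — this is what makes the neuron chemically modulatable and usable as an
event-based chemical sensor.

A canonical Hodgkin–Huxley squid-axon model (`hh_simulate`) is included as
an independent oracle for the spike-analysis layer.

## Worked example

```r
library(coecn)

p <- config_A()                 # 1 uF, 470 kOhm, ~5 Hz reference neuron
resting_state(p)$V_mem
#> [1] 0.175

tr <- simulate_neuron(p, stimulus_program(baseline = 2e-6, t_max = 5),
                      t_span = 5)
summary(tr)
#> c-OECN trace summary: 50001 samples, 5 s
#>   V_mem: median 0.2208 V, max 0.3607 V, min 0.1078 V
#>   spikes: 25 (steady rate 4.99 Hz)
```

The neuron rests at 175 mV; a constant 2 uA input produces tonic spiking at
5.0 Hz with a ~0.35 V depolarization peak (the onset spike from rest
slightly overshoots the 0.345 V steady peak) and a post-spike undershoot to
0.108 V — below rest, i.e. a genuine hyperpolarization phase. Lowering the
potassium supply voltage makes the K-OECT turn on earlier and switches the
excitability class:

```r
run_class_switch_scan(config_A(), c(-0.05, -0.065, -0.07, -0.072))
#>    E_K_V                  label
#> 1 -0.050                 class1
#> 2 -0.065                 class2
#> 3 -0.070 class3_phasic_bursting
#> 4 -0.072  class3_phasic_spiking
```

The same transition is driven chemically by Ca2+ in the K-OECT electrolyte
(`run_ca_modulation`), and event-based sensing configurations spike only in
chosen concentration windows:

```r
sc <- sensing_config("nacl")
run_concentration_scan(sc$params, sc$rule)
#> Event sensing: NaCl (mM)
#>   concentration n_spikes spiking
#> 1          12.5        1   FALSE
#> 2          25.0        1   FALSE
#> 3          50.0       14    TRUE
#> 4         100.0       15    TRUE
#>   threshold: 25 mM (largest non-spiking concentration)
```

Other entry points: `f_i_curve` (rate vs input current),
`feature_battery` (tonic spiking, latency, integration, refractoriness,
resonance, threshold variability, rebound, accommodation, excitability
class), `run_skipping_ensemble` (noise-driven stochastic spike skipping),
`run_gaba_inhibition` (neurotransmitter gating), `energy_metrics`
(peak power and energy per spike) and `hh_simulate`.

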