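# Reference configuration A: 1 uF external membrane capacitor, 470 kOhm
# delay resistor, ~5 Hz tonic spiking at 2 uA. Device constants are
# calibration values (see ?config_A).
preset: config_A
stimulus:
  baseline_A: 2.0e-6
simulation:
  t_span_s: 5
  dt_out_s: 1.0e-4
  method: lsoda
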