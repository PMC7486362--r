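# State-transition sequence statistics for strongly coupled ten-unit
# networks under trains of identical stimuli (duration 20, one pulse per
# 1000 time units).  Set model.depression_enabled=false for the control.
model:
  a: 6.25
  b: 1.25
  alpha: 0.2
  beta: 0.04
  theta: 5.0
  w_self: 40.0
  depression_enabled: true
network:
  n_units: 10
  mu: -0.2
  sigma: 1.0
  seed: 2026
  n_networks: 20
stimulus:
  tau_dur: 20.0
  I_app: 1.0
  n_pulses: 12
  tau_isi: 1000.0
  target_fraction: 1.0
  amplitude_draw: fixed
experiment:
  type: sequences
  max_starts: 8
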