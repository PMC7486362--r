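# Reachable-final-state count for a weakly coupled five-unit circuit:
# perturb the settled attractor 01001 with uniform square pulses over a
# duration x amplitude grid and count distinct settled binary patterns.
model:
  a: 6.25
  b: 1.25
  alpha: 0.2
  beta: 0.04
  theta: 5.0
  w_self: 40.0
  depression_enabled: true
network:
  n_units: 5
  mu: 0.0
  sigma: 0.1
  seed: 3
experiment:
  type: reachable
  initial_pattern: "01001"
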