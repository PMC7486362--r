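# Projected basins of attraction of two symmetrically cross-coupled
# bistable units in the (r1, r2) rate plane.  Swap in a weight file with
# negative off-diagonal entries to study mutual inhibition.
model:
  a: 6.25
  b: 1.25
  alpha: 0.2
  beta: 0.04
  theta: 5.0
  w_self: 40.0
  depression_enabled: true
network:
  n_units: 2
  mu: 0.5        # symmetric cross-excitation of +0.5
  sigma: 0.0
  seed: 1
experiment:
  type: basins
  resolution: 101
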