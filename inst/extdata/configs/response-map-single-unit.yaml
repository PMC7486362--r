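# Two-pulse history-dependence map of a single bistable unit with
# short-term synaptic depression: scan pulse duration x amplitude and
# count binarized switches across two identical presentations.
model:
  a: 6.25
  b: 1.25
  alpha: 0.2
  beta: 0.04
  theta: 5.0
  w_self: 40.0
  depression_enabled: true
network:
  n_units: 1
  seed: 1
stimulus:
  tau_isi: 1000.0
experiment:
  type: response-map
  pulses: 2
  max_tau_dur: 100.0
  max_I_app: 4.0
  n_dur: 51
  n_amp: 41
  initial_pattern: "0"
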