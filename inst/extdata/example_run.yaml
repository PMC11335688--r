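# Desk-scale example configuration: a 200-neuron striatum-like network.
# Omitted fields take the full-model defaults (1995 neurons, Table-style
# membrane constants, GABAergic coupling, 5 mm neighbourhood, k = 20/100).
seed: 42
builder:
  n_total: 200
  n_msn: 186
  k_msn: 8
  k_fs: 40
  volume: [4.0, 3.0, 2.5]
  p_rewire: 0.05
sim:
  duration: 200.0
  I0: 10.0
eqfree:
  ensemble: 5
  S_mesh: [0.0, 0.2, 0.4, 0.6, 0.8, 1.0]
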