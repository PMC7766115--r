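# Infinite-diameter reference: tethered coil ejecting through the pore.
system:
  N: 1024
  dinf: true
protocol:
  Lp: 1.0
  max_time: 5.0e+7
output:
  n_runs: 500
  seed: 20209
  sample_interval: 5.0
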