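# gN = 10, gF = 0: longest chain at the bacteriophage-like packing.
system:
  N: 1024
  phi0: 0.4
protocol:
  Lp: 1.0
  max_time: 2.0e+6
output:
  n_runs: 500
  seed: 20201
  sample_interval: 1.0
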