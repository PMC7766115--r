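# gN = 10, gF = 4: phi0 = 0.025, nucleation-dominated regime.
system:
  N: 1024
  phi0: 0.025
protocol:
  Lp: 1.0
  max_time: 1.0e+7
output:
  n_runs: 500
  seed: 20205
  sample_interval: 2.0
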