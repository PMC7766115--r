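# Pore-length study base case (N = 32, phi0 = 0.2); run with
# --lp 1 .. --lp 5 to sweep the channel length.
system:
  N: 32
  phi0: 0.2
protocol:
  Lp: 1.0
  max_time: 2.0e+5
output:
  n_runs: 500
  seed: 20213
  sample_interval: 0.5
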