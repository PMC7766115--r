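# Full-scale campaign configurations

These configurations reproduce the full study campaigns (chain lengths up
to N = 1024, 500 independent runs per case). They are cluster-scale inputs,
not CI tests: a single N = 1024 case takes on the order of days on one CPU.

The case lattice is N = 2^gN, phi0 = 0.4 * 2^-gF, D = (2.5 * 2^(gN+gF))^(1/3),
generated programmatically with `grid_cases(gN, gF)`. Run a case with

    inst/cli/polyeject.R simulate --config <file> --out traces/

or sweep the grid with the `campaign` subcommand. The pore-length study
(`Lp` from 1 to 5) uses `--lp` overrides on the low-phi0 configs.
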