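# Reference cup-closure condition (F/eta = 4.0, at = 2.8, tau = 10) on the
# coarse CI grid. Load with load_config(); run with run_axisym() or the CLI.
preset: fig2A
params:
  dx: 0.2
  t_max: 150
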