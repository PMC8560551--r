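# Stochastic multi-cup condition: reference mechanics plus Poisson
# nucleation noise (sigma = 8, d = 1.5 um, lambda = 3e-5 /um^3/s).
preset: fig4A
params:
  dx: 0.2
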