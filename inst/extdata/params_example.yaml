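# Example soil parameter file for the oxyresp workbench.
# Areas are per unit sample volume; k15 is the lumped microbial O2 demand
# velocity at 15 degC; lam is the hydraulic-distance scale.
A_a: 1.0
A_w: 1.0
eps: 0.0
sigma: 1.0
tau: 1.0
mu: 3.0
lam: 1.0
k15: 0.0014
Ea: 48000
gamma: 0.0
regime: diffusion_limited
dialect: standard
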