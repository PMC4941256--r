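# Nominal unperturbed cycling parameters, Capan-1-like (Tc = 26 h; nominal
# stand-ins, see package documentation)
mean_G1: 12.0
mean_S: 9.0
mean_G2M: 5.0
cv_G1: 0.25
cv_S: 0.15
cv_G2M: 0.20
max_generation: 5
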