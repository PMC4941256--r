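# Nominal unperturbed cycling parameters, BxPC-3-like (Tc = 22 h; the
# published control-growth values are not reproduced here; these are
# documented nominal stand-ins)
mean_G1: 9.0
mean_S: 8.0
mean_G2M: 5.0
cv_G1: 0.20
cv_S: 0.15
cv_G2M: 0.20
max_generation: 5
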