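# Capan-1, gemcitabine 30 nM: 23% DNA-synthesis-rate reduction with the
# usual recovery timing (half-maximum 18 h); G1 delay nominal.
name: gemcitabine
concentration: 30 nM
modules:
- label: synthS.g01
  effect: synthesis_inhibition
  phase: S
  generations: [0, 1]
  magnitude: 0.23
  window: all
  profile: {kind: recovery, half_max: 18.0, steepness: 3.0, floor: 0.0}
- label: delayG1.g0
  effect: delay
  phase: G1
  generations: [0]
  magnitude: 0.50
  window: all
  profile: {kind: step_window, onset: 0.0, offset: 6.0}
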