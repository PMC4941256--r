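# BxPC-3, gemcitabine 40 nM, 0-6 h exposure: published best-fit cytostatic
# modules (complete initial synthesis inhibition; residual long-term S
# delays of 0.37 in generation 0 after 18 h and 0.18 in generation 1 after
# 21 h). Death-commitment rates are plotted, not printed, in the source
# and are therefore not encoded here; compose death modules explicitly if
# needed (generation 0 after 48 h, generation 1 after 72 h).
name: gemcitabine
concentration: 40 nM
modules:
- label: delayG1.g0
  effect: delay
  phase: G1
  generations: [0]
  magnitude: 0.87
  window: all
  profile: {kind: step_window, onset: 0.0, offset: 15.0}
- label: synthS.g01
  effect: synthesis_inhibition
  phase: S
  generations: [0, 1]
  magnitude: 1.0
  window: all
  profile: {kind: recovery, half_max: 18.0, steepness: 3.0, floor: 0.0}
- label: ltDelayS.g0
  effect: delay
  phase: S
  generations: [0]
  magnitude: 0.37
  window: all
  profile: {kind: step_window, onset: 18.0, offset: .inf}
- label: ltDelayS.g1
  effect: delay
  phase: S
  generations: [1]
  magnitude: 0.18
  window: all
  profile: {kind: step_window, onset: 21.0, offset: .inf}
- label: blockG2M.g0
  effect: block
  phase: G2M
  generations: [0]
  magnitude: 0.15
  window: all
  profile: {kind: step_window, onset: 12.0, offset: .inf}
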