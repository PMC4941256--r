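# BxPC-3, gemcitabine 20 nM, 0-6 h exposure: published best-fit modules.
# DNA synthesis is inhibited by 88% immediately and recovers with
# half-maximum at 18 h (recovery timing is not dose dependent); the G1
# delay acts before 6 h; a modest G2M block intercepts generation-0 cells
# reaching G2M after 12 h. Effects persist past washout (window all).
name: gemcitabine
concentration: 20 nM
modules:
- label: delayG1.g0
  effect: delay
  phase: G1
  generations: [0]
  magnitude: 0.75
  window: all
  profile: {kind: step_window, onset: 0.0, offset: 6.0}
- label: synthS.g01
  effect: synthesis_inhibition
  phase: S
  generations: [0, 1]
  magnitude: 0.88
  window: all
  profile: {kind: recovery, half_max: 18.0, steepness: 3.0, floor: 0.0}
- label: blockG2M.g0
  effect: block
  phase: G2M
  generations: [0]
  magnitude: 0.10
  window: all
  profile: {kind: step_window, onset: 12.0, offset: .inf}
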