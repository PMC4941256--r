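# Capan-1, gemcitabine 100 nM: 95% synthesis inhibition, G1 delay like
# BxPC-3 at 40 nM, secondary G2M perturbation; residual long-term S delay
# nominal.
name: gemcitabine
concentration: 100 nM
modules:
- label: synthS.g01
  effect: synthesis_inhibition
  phase: S
  generations: [0, 1]
  magnitude: 0.95
  window: all
  profile: {kind: recovery, half_max: 18.0, steepness: 3.0, floor: 0.0}
- label: ltDelayS.g0
  effect: delay
  phase: S
  generations: [0]
  magnitude: 0.20
  window: all
  profile: {kind: step_window, onset: 18.0, offset: .inf}
- label: delayG1.g0
  effect: delay
  phase: G1
  generations: [0]
  magnitude: 0.87
  window: all
  profile: {kind: step_window, onset: 0.0, offset: 15.0}
- label: blockG2M.g0
  effect: block
  phase: G2M
  generations: [0]
  magnitude: 0.10
  window: all
  profile: {kind: step_window, onset: 12.0, offset: .inf}
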