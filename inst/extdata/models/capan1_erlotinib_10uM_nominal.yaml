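# Capan-1, erlotinib 10 uM: stronger G1/S perturbation of generation-0
# cells, a small G2M checkpoint activity, generation-1 G1 block with
# post-washout release and a slight S delay. Magnitudes nominal.
name: erlotinib
concentration: 10 uM
modules:
- label: delayS.g0
  effect: delay
  phase: S
  generations: [0]
  magnitude: 0.50
  window: during
  profile: {kind: sigmoid, half_max: 6.0, steepness: 1.366}
- label: blockG2M.g0
  effect: block
  phase: G2M
  generations: [0]
  magnitude: 0.05
  window: during
  profile: {kind: sigmoid, half_max: 6.0, steepness: 1.366}
- label: blockG1.g1
  effect: block
  phase: G1
  generations: [1]
  magnitude: 0.60
  window: during
  profile: {kind: constant}
- label: delayS.post.g1
  effect: delay
  phase: S
  generations: [1]
  magnitude: 0.20
  window: post
  profile: {kind: constant}
- label: recycleG1.g1
  effect: recycle
  phase: G1
  generations: [1]
  magnitude: 0.10
  window: post
  profile: {kind: sigmoid, half_max: 0.0, steepness: 1.366}
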