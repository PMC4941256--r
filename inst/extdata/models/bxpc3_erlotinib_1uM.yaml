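# BxPC-3, erlotinib 1 uM, 0-48 h exposure: published best-fit modules.
# Generation-0 delay/block activities rise sigmoidally with half-maximum
# 6 h after treatment start; generation-1 effects are constant during
# exposure. Post-treatment modules act after washout (48 h); the G1
# recycling rate rises with half-maximum at washout.
name: erlotinib
concentration: 1 uM
modules:
- label: delayS.g0
  effect: delay
  phase: S
  generations: [0]
  magnitude: 0.33
  window: during
  profile: {kind: sigmoid, half_max: 6.0, steepness: 1.366}
- label: blockG2M.g0
  effect: block
  phase: G2M
  generations: [0]
  magnitude: 0.11
  window: during
  profile: {kind: sigmoid, half_max: 6.0, steepness: 1.366}
- label: blockG1.g1
  effect: block
  phase: G1
  generations: [1]
  magnitude: 0.23
  window: during
  profile: {kind: constant}
- label: delayS.g1
  effect: delay
  phase: S
  generations: [1]
  magnitude: 0.33
  window: during
  profile: {kind: constant}
- label: deathS.g01
  effect: death
  phase: S
  generations: [0, 1]
  magnitude: 0.010
  window: during
  profile: {kind: constant}
- label: delayS.post.g1
  effect: delay
  phase: S
  generations: [1]
  magnitude: 0.41
  window: post
  profile: {kind: constant}
- label: delayG2M.post.g1
  effect: delay
  phase: G2M
  generations: [1]
  magnitude: 0.19
  window: post
  profile: {kind: constant}
- label: recycleG1.g01
  effect: recycle
  phase: G1
  generations: [0, 1]
  magnitude: 0.03
  window: post
  profile: {kind: sigmoid, half_max: 0.0, steepness: 1.366}
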