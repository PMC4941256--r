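# Capan-1, erlotinib 1 uM: the published model needs only a moderate G1
# block in generation 1 with release after washout; magnitudes here are
# nominal (not printed in the main text).
name: erlotinib
concentration: 1 uM
modules:
- label: blockG1.g1
  effect: block
  phase: G1
  generations: [1]
  magnitude: 0.30
  window: during
  profile: {kind: constant}
- label: recycleG1.g1
  effect: recycle
  phase: G1
  generations: [1]
  magnitude: 0.10
  window: post
  profile: {kind: constant}
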