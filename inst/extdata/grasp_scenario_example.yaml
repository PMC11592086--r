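# Example grasp scenario: a moderately stiff cup met at theta1 = 0.5 rad.
object:
  stiffness: 800
  theta_touch: 0.5
  label: example cup
profile:
  times: [0, 0.05, 0.4, 2.0]
  levels: [0, 0, 0.1, 0.1]
seed: 1
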