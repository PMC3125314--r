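name: arabinose
states:
- x1
- x2
inputs:
- u
notes: Feedforward activation cascade; hierarchical, hence iteratively solvable.
terms:
- label: c1
  target: x1
  kind: c
  args:
  - ~
  tags:
  - positive-constant
- label: c1u
  target: x1
  kind: c
  args:
  - u
  tags:
  - sigmoidal
- label: b11
  target: x1
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x1
- label: c2u1
  target: x2
  kind: c
  args:
  - u
  - x1
  tags:
  - sigmoidal
  - increasing-asymptotically-constant
- label: b22
  target: x2
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x2
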