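name: lac
states:
- x1
- x2
- x3
inputs:
- u
notes: 'Reduced model: the enzyme readout is slaved to the inducer equilibrium and
  tracked separately; the linear external-inducer inflow is neglected.'
terms:
- label: c13
  target: x1
  kind: c
  args:
  - x3
  tags:
  - constant-sigmoidal
- label: b11
  target: x1
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x1
- label: a21
  target: x2
  kind: a
  args:
  - ~
  tags:
  - positive-constant
  mult: x1
- label: b22
  target: x2
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x2
- label: a32
  target: x3
  kind: a
  args:
  - u
  tags:
  - increasing-asymptotically-constant
  mult: x2
- label: b32
  target: x3
  kind: b
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x2
  a5: yes
- label: b33
  target: x3
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x3
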