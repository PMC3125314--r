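name: srna
states:
- x1
- x2
inputs: []
notes: Stoichiometric mutual degradation; the coupled terms share the binding rate.
terms:
- label: c1
  target: x1
  kind: c
  args:
  - ~
  tags:
  - positive-constant
- label: b11
  target: x1
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x1
- label: b12
  target: x1
  kind: b
  args:
  - x1
  tags:
  - increasing-asymptotically-unbounded
  mult: x2
  coupling: k
  a5: yes
- label: c2
  target: x2
  kind: c
  args:
  - ~
  tags:
  - positive-constant
- label: b22
  target: x2
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x2
- label: b21
  target: x2
  kind: b
  args:
  - x2
  tags:
  - increasing-asymptotically-unbounded
  mult: x1
  coupling: k
  a5: yes
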