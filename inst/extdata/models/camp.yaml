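name: camp
states:
- x1
- x2
- x3
inputs:
- u
notes: Activation terms vanish exactly at the total-amount thresholds, so the actives
  stay below their totals (mass conservation).
terms:
- label: a1u
  target: x1
  kind: a
  args:
  - x1
  tags:
  - decreasing-exactly-null
  mult: u
- label: b11
  target: x1
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x1
- label: a23
  target: x2
  kind: a
  args:
  - x2
  tags:
  - decreasing-exactly-null
  mult: x3
- label: b22
  target: x2
  kind: b
  args:
  - ~
  tags:
  - positive-constant
  mult: x2
- label: d32
  target: x3
  kind: d
  args:
  - x2
  tags:
  - decreasing-asymptotically-null
- label: a31
  target: x3
  kind: a
  args:
  - x2
  tags:
  - decreasing-asymptotically-null
  mult: x1
- label: b32
  target: x3
  kind: b
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x2
  a5: yes
- label: g33
  target: x3
  kind: b
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x3
  absorbed: yes
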