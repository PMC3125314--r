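name: mapk-constant
states:
- x1
- x2
- x3
- x4
- x5
- x6
- x7
inputs: []
notes: Positive feedback strength mu lives in the a17 amplitude; the basal drive must
  stay below the top-tier removal ceiling or no equilibrium is possible.
terms:
- label: c10
  target: x1
  kind: c
  args:
  - ~
  tags:
  - positive-constant
- label: a17
  target: x1
  kind: a
  args:
  - x1
  tags:
  - nonnegative-constant
  mult: x7
- label: g11
  target: x1
  kind: b
  args:
  - x1
  tags:
  - increasing-asymptotically-constant
  mult: x1
  absorbed: yes
- label: c23
  target: x2
  kind: c
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  coupling: g33
- label: b21
  target: x2
  kind: b
  args:
  - x2
  tags:
  - increasing-asymptotically-constant
  mult: x1
  coupling: phos2
  a5: yes
- label: a31
  target: x3
  kind: a
  args:
  - x2
  tags:
  - increasing-asymptotically-constant
  mult: x1
  coupling: phos2
- label: c34
  target: x3
  kind: c
  args:
  - x4
  tags:
  - increasing-asymptotically-constant
  coupling: g44
- label: b31
  target: x3
  kind: b
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x1
  coupling: phos3
  a5: yes
- label: g33
  target: x3
  kind: b
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x3
  coupling: g33
  absorbed: yes
- label: a41
  target: x4
  kind: a
  args:
  - x3
  tags:
  - increasing-asymptotically-constant
  mult: x1
  coupling: phos3
- label: g44
  target: x4
  kind: b
  args:
  - x4
  tags:
  - increasing-asymptotically-constant
  mult: x4
  coupling: g44
  absorbed: yes
- label: c56
  target: x5
  kind: c
  args:
  - x6
  tags:
  - increasing-asymptotically-constant
  coupling: g66
- label: b54
  target: x5
  kind: b
  args:
  - x5
  tags:
  - increasing-asymptotically-constant
  mult: x4
  coupling: phos5
  a5: yes
- label: a64
  target: x6
  kind: a
  args:
  - x5
  tags:
  - increasing-asymptotically-constant
  mult: x4
  coupling: phos5
- label: c67
  target: x6
  kind: c
  args:
  - x7
  tags:
  - increasing-asymptotically-constant
  coupling: g77
- label: b64
  target: x6
  kind: b
  args:
  - x6
  tags:
  - increasing-asymptotically-constant
  mult: x4
  coupling: phos6
  a5: yes
- label: g66
  target: x6
  kind: b
  args:
  - x6
  tags:
  - increasing-asymptotically-constant
  mult: x6
  coupling: g66
  absorbed: yes
- label: a74
  target: x7
  kind: a
  args:
  - x6
  tags:
  - increasing-asymptotically-constant
  mult: x4
  coupling: phos6
- label: g77
  target: x7
  kind: b
  args:
  - x7
  tags:
  - increasing-asymptotically-constant
  mult: x7
  coupling: g77
  absorbed: yes
conserved:
- states:
  - x2
  - x3
  - x4
  label: MEK total
- states:
  - x5
  - x6
  - x7
  label: MAPK total
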