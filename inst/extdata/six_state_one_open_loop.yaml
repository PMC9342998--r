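name: 6-state-1-open-loop
states:
- C1
- C2
- C3
- O4
- C5
- C6
edges:
- from: C1
  to: C2
  param: kon1
  ligand: 1.0
- from: C2
  to: C1
  param: koff1
  ligand: 0.0
- from: C2
  to: C3
  param: kb23
  ligand: 1.0
- from: C3
  to: C2
  param: ku32
  ligand: 0.0
- from: C3
  to: O4
  param: kopen
  ligand: 0.0
- from: O4
  to: C3
  param: kclose
  ligand: 0.0
- from: C2
  to: C5
  param: kc25
  ligand: 0.0
- from: C5
  to: C2
  param: kc52
  ligand: 0.0
- from: C5
  to: C6
  param: kb56
  ligand: 1.0
- from: C6
  to: C5
  param: ku65
  ligand: 0.0
- from: C6
  to: C3
  param: kc63
  ligand: 0.0
- from: C3
  to: C6
  param: kc36
  ligand: 0.0
conducting:
- 0.0
- 0.0
- 0.0
- 1.0
- 0.0
- 0.0
bound_ligands:
- 0
- 1
- 2
- 2
- 1
- 2
loops:
- target: ku32
  numer:
  - kb23
  - kc36
  - ku65
  - kc52
  denom:
  - kc25
  - kb56
  - kc63
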