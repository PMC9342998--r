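name: CCCO
states:
- C1
- C2
- C3
- O4
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
  param: kon2
  ligand: 1.0
- from: C3
  to: C2
  param: koff2
  ligand: 0.0
- from: C3
  to: O4
  param: kopen
  ligand: 0.0
- from: O4
  to: C3
  param: kclose
  ligand: 0.0
conducting:
- 0.0
- 0.0
- 0.0
- 1.0
bound_ligands:
- 0
- 1
- 2
- 2
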