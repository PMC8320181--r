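# Two-basin synthetic macrocycle-like torsional ensemble (8 ring torsions).
n_conformers: 400
origin_label: demo
seed: 42
basins:
  - label: A
    weight: 0.7
    mean_angles: [60, -120, 60, -120, 60, -120, 60, -120]
    concentration: 20
  - label: B
    weight: 0.3
    mean_angles: [-75, 105, -75, 105, -75, 105, -75, 105]
    concentration: 20
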