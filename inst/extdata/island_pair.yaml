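name: island-pair
deme_side_km: 150
origin: [1, 1]
grid: |
  LL
samples:
  - {pop: A, row: 1, col: 1, "n": 10, group: AFR}
  - {pop: B, row: 1, col: 2, "n": 10, group: ENA}
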