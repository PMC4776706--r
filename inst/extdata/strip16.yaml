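name: strip-16
deme_side_km: 150
origin: [1, 1]
grid: |
  LLLLLLLLLLLLLLLL
samples:
  - {pop: P1, row: 1, col: 2, "n": 10, group: AFR}
  - {pop: P2, row: 1, col: 6, "n": 10, group: ENA}
  - {pop: P3, row: 1, col: 11, "n": 10, group: CAS}
  - {pop: P4, row: 1, col: 16, "n": 10, group: EAS}
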