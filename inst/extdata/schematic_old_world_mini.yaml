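name: schematic-old-world-mini
deme_side_km: 150
origin: [10, 6]
grid: |
  .LLLLLLLLLLLLLLLLLLLLLL.
  .LLLLLLLLLLLLLLLLLLLLLL.
  .RRRRRRRRRLLLLLLLLLLLLL.
  .......C..LBBLLLLLLLLL..
  .......C..LLLLLLLLLLLL..
  .RRRRRRL..LLRRRRRRRRRR..
  .BBBBBLL..LLRRRRRRRRRR..
  .RRRRRRR..LLRRRRRRRRRR..
  .RRRRRRR................
  .RRRRRRR................
  .RRRRRRR................
  .RRRRRRR................
samples:
  - {pop: AFR1, row: 9, col: 3, "n": 8, group: AFR}
  - {pop: AFR2, row: 11, col: 6, "n": 8, group: AFR}
  - {pop: AFR3, row: 10, col: 8, "n": 8, group: AFR}
  - {pop: ENA1, row: 2, col: 4, "n": 8, group: ENA}
  - {pop: ENA2, row: 3, col: 7, "n": 8, group: ENA}
  - {pop: ENA3, row: 6, col: 4, "n": 8, group: ENA}
  - {pop: CAS1, row: 1, col: 12, "n": 8, group: CAS}
  - {pop: CAS2, row: 2, col: 15, "n": 8, group: CAS}
  - {pop: CAS3, row: 1, col: 17, "n": 8, group: CAS}
  - {pop: EAS1, row: 2, col: 20, "n": 8, group: EAS}
  - {pop: EAS2, row: 3, col: 22, "n": 8, group: EAS}
  - {pop: EAS3, row: 6, col: 20, "n": 8, group: EAS}
crossings:
  - [[8, 8], [7, 11]]
  - [[6, 2], [3, 2]]
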