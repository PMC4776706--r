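name: schematic-old-world-small
deme_side_km: 150
origin: [20, 18]
grid: |
  ............................................................
  ............................................................
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLL..
  .....LLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLLBBBBBBBBBLLLLLLLLLLLL..
  .....RRRRRRRRRRRRRRRRRRRLLLLLLLLLLLLLBBBBBBBBBLLLLLLLLLLLL..
  ...................C...BBBBBBBBB.LLLLLLLLLLLLLLLLLLLLLLL....
  ...................C...BBBBBBBBB.LLLLLLLLLLLLLLLLLLLLLLL....
  ...RRRRRRRRRRRRRRRRL...BBBBBBBBB.LLRRRRRRRRRRRRRRRRRRRRR....
  ...LLLLLLLLLLLLLLLLL..LLLLLLLLLLLLLRRRRRRRRRRRRRRRRRRRRR....
  ...BBBBBBBBBBBBLLLLL.............LLRRRRRRRRRRRRRRRRRRRRR....
  ...BBBBBBBBBBBBLLLLL.............LLRRRRRRRRRRRRRRRRRRRRR....
  ...RRRRRRRRRRRRRRRRR.............LLRRRRRRRRRRRRRRRRRRRRR....
  ...RRRRRRRRRRRRRRRRR.............LLRRRRRRRRRRRRRRRRRRRRR....
  ...RRRRRRRRRRRRRRRRR.............LLRRRRRRRRRRRRRRRRRRRRR....
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ...RRRRRRRRRRRRRRRRR........................................
  ............................................................
samples:
  - {pop: AFR1, row: 20, col: 8, "n": 15, group: AFR}
  - {pop: AFR2, row: 22, col: 12, "n": 15, group: AFR}
  - {pop: AFR3, row: 25, col: 16, "n": 15, group: AFR}
  - {pop: AFR4, row: 19, col: 14, "n": 15, group: AFR}
  - {pop: AFR5, row: 27, col: 8, "n": 15, group: AFR}
  - {pop: AFR6, row: 24, col: 19, "n": 15, group: AFR}
  - {pop: ENA1, row: 5, col: 10, "n": 15, group: ENA}
  - {pop: ENA2, row: 8, col: 14, "n": 15, group: ENA}
  - {pop: ENA3, row: 11, col: 8, "n": 15, group: ENA}
  - {pop: ENA4, row: 6, col: 20, "n": 15, group: ENA}
  - {pop: ENA5, row: 9, col: 24, "n": 15, group: ENA}
  - {pop: ENA6, row: 14, col: 10, "n": 15, group: ENA}
  - {pop: CAS1, row: 5, col: 32, "n": 15, group: CAS}
  - {pop: CAS2, row: 7, col: 36, "n": 15, group: CAS}
  - {pop: CAS3, row: 6, col: 40, "n": 10, group: CAS}
  - {pop: CAS4, row: 8, col: 30, "n": 15, group: CAS}
  - {pop: EAS1, row: 5, col: 50, "n": 15, group: EAS}
  - {pop: EAS2, row: 8, col: 52, "n": 15, group: EAS}
  - {pop: EAS3, row: 11, col: 55, "n": 15, group: EAS}
  - {pop: EAS4, row: 16, col: 50, "n": 15, group: EAS}
  - {pop: EAS5, row: 18, col: 44, "n": 15, group: EAS}
  - {pop: EAS6, row: 4, col: 46, "n": 10, group: EAS}
crossings:
  - [[16, 20], [15, 23]]
  - [[14, 6], [11, 6]]
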