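# Per-zone generator targets: sample counts and per-metal summary statistics
# (mg/kg) of the Guangzhou road-dust survey the synthetic generator emulates.
# `min`/`max` are the printed observed ranges; where a printed range is
# mutually inconsistent with the printed mean +/- SD (it happens for several
# agricultural entries and a couple of heavy-tailed rows), the generator
# detects this, drops the bounds for that metal, and flags the row rather
# than silently resolving the conflict.
zones:
  industrial:
    "n": 23
    metals:
      As: {mean: 18.4, sd: 12.6, min: 1.7, max: 50.4}
      Cd: {mean: 0.74, sd: 0.52, min: 0.22, max: 2.27}
      Cr: {mean: 200, sd: 266, min: 24.1, max: 1260}
      Pb: {mean: 166, sd: 177, min: 29.9, max: 806}
      Cu: {mean: 133, sd: 154, min: 16.2, max: 625}
      Zn: {mean: 640, sd: 493, min: 46.9, max: 1770}
      Ni: {mean: 34.8, sd: 33.0, min: 8.0, max: 152}
      V: {mean: 37.3, sd: 11.1, min: 15.14, max: 63.9}
  traffic:
    "n": 20
    metals:
      As: {mean: 25.1, sd: 18.3, min: 4.7, max: 61.2}
      Cd: {mean: 0.72, sd: 0.72, min: 0.23, max: 3.14}
      Cr: {mean: 116, sd: 71.9, min: 34.4, max: 347}
      Pb: {mean: 115, sd: 90.9, min: 47.1, max: 440}
      Cu: {mean: 116, sd: 125, min: 23.8, max: 599}
      Zn: {mean: 368, sd: 166, min: 162, max: 761}
      Ni: {mean: 41.2, sd: 40.7, min: 10.7, max: 201}
      V: {mean: 41.0, sd: 13.1, min: 18.3, max: 61.8}
  agricultural:
    "n": 5
    metals:
      As: {mean: 19.2, sd: 5.7, min: 12.8, max: 23.8}
      Cd: {mean: 0.74, sd: 0.74, min: 0.31, max: 2.05}
      Cr: {mean: 55.7, sd: 16.6, min: 35.2, max: 73.5}
      Pb: {mean: 219, sd: 314, min: 77.4, max: 259}
      Cu: {mean: 46.9, sd: 55.8, min: 45.9, max: 171}
      Zn: {mean: 143, sd: 57.5, min: 236, max: 558}
      Ni: {mean: 15.1, sd: 3.6, min: 24.9, max: 46.0}
      V: {mean: 41.6, sd: 6.4, min: 34.2, max: 47.3}
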