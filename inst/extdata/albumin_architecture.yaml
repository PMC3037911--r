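region_length: 162000.0
loops:
- id: L1
  anchor_left: 0.0
  anchor_right: 32400.0
  tip: 16200.0
- id: L2
  anchor_left: 32400.0
  anchor_right: 64800.0
  tip: 48600.0
- id: L3
  anchor_left: 64800.0
  anchor_right: 97200.0
  tip: 81000.0
- id: L4
  anchor_left: 97200.0
  anchor_right: 129600.0
  tip: 113400.0
- id: L5
  anchor_left: 129600.0
  anchor_right: 162000.0
  tip: 145800.0
amplicons:
- id: a
  start: 5863.0
  end: 6138.0
  chromosome: chr14
- id: b
  start: 15727.0
  end: 16274.0
  chromosome: chr14
- id: c
  start: 25813.0
  end: 26187.0
  chromosome: chr14
- id: d
  start: 35848.0
  end: 36153.0
  chromosome: chr14
- id: e
  start: 45809.0
  end: 46191.0
  chromosome: chr14
- id: f
  start: 55804.0
  end: 56197.0
  chromosome: chr14
- id: g
  start: 65748.0
  end: 66252.0
  chromosome: chr14
- id: h
  start: 75869.0
  end: 76132.0
  chromosome: chr14
- id: i
  start: 85768.0
  end: 86233.0
  chromosome: chr14
- id: j
  start: 95804.0
  end: 96196.0
  chromosome: chr14
- id: k
  start: 105874.0
  end: 106126.0
  chromosome: chr14
- id: l
  start: 115814.0
  end: 116187.0
  chromosome: chr14
- id: m
  start: 125883.0
  end: 126117.0
  chromosome: chr14
- id: 'n'
  start: 135823.0
  end: 136178.0
  chromosome: chr14
- id: o
  start: 145864.0
  end: 146136.0
  chromosome: chr14
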