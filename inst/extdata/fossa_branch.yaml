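branches:
  - attach_x_mm: 25
    length_mm: 19
    area_mm2: 30
    closed_end: true
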