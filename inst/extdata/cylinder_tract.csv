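x_mm,area_mm2
0,706.858
142,706.858
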