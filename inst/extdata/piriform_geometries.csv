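singer,vowel,length_mm,antires_hz,vtv_cm3,pv_cm3,ratio_pct
Maristela,haad,17.63,4741,44.58,3.47,7.78
Bartholomew,haad,18.31,4565,37.32,1.7,4.56
Barnaby,haad,20.50,4077,80.49,1.69,2.1
Barnaby,pot,19.97,4185,65.61,3.64,5.55
Barnaby,stone,19.00,4399,65.29,3.43,5.25
Barnaby,food,19.42,4304,57.67,4.79,8.31
Barnaby,neap,21.18,3946,65.48,3.58,5.47
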