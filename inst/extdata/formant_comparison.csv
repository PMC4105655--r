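vowel,formant,num_hz,exp_hz
pot,F1,417,482
pot,F2,834,833
pot,F3,2334,2448
pot,F4,2647,2753
pot,F5,3414,3515
stone,F1,483,523
stone,F2,1134,1043
stone,F3,2302,2256
stone,F4,2778,2719
stone,F5,3625,3173
food,F1,264,283
food,F2,867,821
food,F3,2122,2193
food,F4,2736,2774
food,F5,3361,3464
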