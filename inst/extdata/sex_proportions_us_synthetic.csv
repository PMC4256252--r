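"base_age","prop_female"
55,0.52
60,0.53
65,0.54
70,0.55
75,0.57
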