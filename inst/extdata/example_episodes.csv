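behavior,onset_s,offset_s
resting,0.500000,6.250000
grooming,7.000000,11.500000
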