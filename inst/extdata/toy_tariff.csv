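dimension,level,decrement
mobility,1,0.00
mobility,2,0.10
mobility,3,0.25
selfcare,1,0.00
selfcare,2,0.08
selfcare,3,0.22
activities,1,0.00
activities,2,0.09
activities,3,0.24
pain,1,0.00
pain,2,0.12
pain,3,0.28
anxiety,1,0.00
anxiety,2,0.11
anxiety,3,0.26
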