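species_id,temperature,moisture,nutrients,light
s1,1,2,1,3
s2,2,3,2,4
s3,3,3,3,4
s4,4,4,4,5
s5,5,,5,3
s6,3,2,,4
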