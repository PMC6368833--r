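site_id,period,surveyor,species_id
A,1,regular,s1
A,1,regular,s2
A,1,regular,s3
A,1,regular,genus_x
A,2,regular,s2
A,2,regular,s3
A,2,regular,s4
A,3,regular,s4
A,3,regular,s5
A,1,replicate,s1
A,1,replicate,s3
B,1,regular,s1
B,1,regular,s5
B,2,regular,s1
B,2,regular,s5
B,3,regular,s1
B,3,regular,s2
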