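site_id,temp_c,precip_mm,ndep2000,ndep2015,inclination_deg,elevation_m
A,5.2,1300,18.0,15.5,12,1250
B,7.8,1100,24.0,20.0,25,850
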