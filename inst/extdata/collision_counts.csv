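condition,photostate,phase,n_merged,n_bounced,observation_time_s
trans LODs,trans,LOD,30,19,200
trans LDDs,trans,LDD,53,42,80
cis LODs,cis,LOD,9,10,210
cis LDDs,cis,LDD,21,86,60
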