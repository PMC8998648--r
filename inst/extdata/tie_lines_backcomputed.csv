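photostate,phase,DPhPC_like,DPPC_like,Chol
trans,LOD,0.035,0.570,0.395
trans,LDD,0.530,0.180,0.290
cis,LOD,0.070,0.390,0.540
cis,LDD,0.670,0.080,0.250
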