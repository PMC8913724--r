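group,c_p,c_d
Lumbar extensor,0.50,0.23
Lumbar flexor,0.48,0.11
Hip extensor,0.45,0.05
Hip flexor,0.50,0.16
Knee extensor,0.33,0.05
Knee flexor,0.28,0.23
Ankle extensor,0.17,0.06
Ankle flexor,0.30,0.27
Subtalar evertor,0.50,0.11
Subtalar invertor,0.50,0.05
Biarticular,0.39,0.05
Neck extensor,0.17,0.06
Neck flexor,0.17,0.27
Neck biarticular,0.17,0.06
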