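sample_id,NP,VI_ml,r,VF_ml
case1,78,50,0.001,0.1
case1,82,50,0.001,0.1
case2,64,50,0.001,0.1
case2,58,50,0.001,0.1
case6,80,50,0.001,0.1
case6,76,50,0.001,0.1
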