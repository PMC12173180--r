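sample_id,cn,sv,cp,cfpp,iv,density,du,hhv
PW,61,179,5.1,5.6,72,0.8,74,35
BG-11,59,186,6,7.7,74,0.8,76,36
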