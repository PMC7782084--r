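group,n_single_ctc,dapi_evaluable,dapi_single,dapi_double,dapi_clustered
breast,48934,38918,38211,682,25
prostate,19117,13356,13127,224,5
colorectal,503,255,252,3,0
bladder,182,99,92,4,2
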