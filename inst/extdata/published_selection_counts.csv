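group,material,single,doublet,small_cluster,large_cluster,printed_total
breast,blood,44232,1172,68,1,45472
breast,liquor,4702,513,104,3,5322
prostate,blood,19117,916,63,4,20100
colorectal,blood,503,12,3,1,519
bladder,blood,182,15,1,0,198
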