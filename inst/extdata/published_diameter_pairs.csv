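label,median_area,printed_cd
breast_ctc_blood,120.4,12.4
breast_ctc_liquor,141.3,13.4
breast_cell_line,265.4,18.4
mcf7,241.7,17.54
prostate_ctc,83.6,10.3
lncap,337.9,20.7
colorectal_ctc,44.6,7.5
bladder_ctc,57.8,8.6
leukocyte,69.6,9.4
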