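label,median_nucleus_area,median_cell_area,printed_ncr
breast_ctc_blood,56.1,120.4,0.47
breast_ctc_liquor,64.3,141.3,0.46
breast_cell_line,94.2,265.4,0.37
prostate_ctc,52.0,83.6,0.62
prostate_cell_line,161.0,337.9,0.48
colorectal_ctc,26.83,44.6,0.60
bladder_ctc,43.4,57.8,0.75
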