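group,material,n_single,median_area,iqr_area,printed_cd,median_nucleus_area,iqr_nucleus_area,printed_ncr,n_dapi_single
breast,blood,44232,120.4,104.9,12.4,56.1,41.8,0.47,33696
breast,liquor,4702,141.3,113.1,13.4,64.3,36.9,0.46,4515
prostate,blood,19117,83.6,63.5,10.3,52.0,35.2,0.62,13127
colorectal,blood,503,44.6,53.3,7.5,26.83,29.0,0.60,252
bladder,blood,182,57.8,111.5,8.6,43.4,33.6,0.75,93
breast_cell_line,blood,3395,265.4,127.38,18.4,94.2,50,0.37,NA
prostate_cell_line,blood,1054,337.9,142.5,20.7,161.0,2.85,0.48,NA
leukocyte,blood,130,69.6,25.6,9.4,NA,NA,NA,NA
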