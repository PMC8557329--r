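subject_id,phenotype,mean_intensity_au,intensity_sd,pct_positive,pct_positive_sd,wb_pct_of_ctrl
CTRL,CTRL,50387,2778,99.5,0.6,100
P1,mildBMD,23228,185,99,1.4,54
P2,mildBMD,33684,836,98.5,0.7,54
P3,mildBMD,28519,375,99.5,0.7,76
P4,severeBMD,30798,86,100,0,NA
P5,severeBMD,13657,589,81.5,2.1,17
P6,IMD,17064,1367,75.5,3.5,NA
P7,IMD,19168,860,98.5,0.7,NA
P8,IMD,18726,1393,98.5,0.7,NA
P9,DMD,8694,498,37,4.2,NA
P10,DMD,13551,1568,71.5,6.4,0
P11,DMD,12572,552,52.5,2.1,12
P12,DMD,12168,961,49.5,0.7,0
P13,DMD,11539,988,53,4.2,0
P14,DMD,13161,529,29.5,0.7,NA
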