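sample_id,repeat_index,dys_au,actinin_au,is_control
CTRL_A,1,1850,1900,TRUE
CTRL_A,2,1795,1840,TRUE
CTRL_A,3,1910,1965,TRUE
CTRL_A,4,1788,1835,TRUE
mildBMD_1,1,1015,1880,FALSE
mildBMD_1,2,980,1810,FALSE
mildBMD_1,3,1060,1930,FALSE
mildBMD_1,4,1005,1870,FALSE
severeBMD_5,1,320,1905,FALSE
severeBMD_5,2,305,1860,FALSE
severeBMD_5,3,330,1940,FALSE
severeBMD_5,4,318,1890,FALSE
DMD_11,1,225,1915,FALSE
DMD_11,2,204,1850,FALSE
DMD_11,3,242,1955,FALSE
DMD_11,4,218,1895,FALSE
DMD_12,1,0,1900,FALSE
DMD_12,2,0,1845,FALSE
DMD_12,3,0,1925,FALSE
DMD_12,4,0,1872,FALSE
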