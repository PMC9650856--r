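term,period,coefficient,rss,se,significant
sl,dry,0.031216,1.031709,0.006206,FALSE
log_sl,dry,-0.066014,0.936118,0.006020,TRUE
andvi,dry,0.220561,1.246776,0.025554,TRUE
dndvi,dry,-0.118859,0.887933,0.040020,TRUE
elev,dry,0.033046,1.033598,0.007553,TRUE
tri,dry,-0.069324,0.933025,0.005778,TRUE
temp,dry,-0.018336,0.981831,0.008080,TRUE
experience,dry,0.013913,1.014010,0.032343,FALSE
group_size,dry,-0.002478,0.997526,0.005738,FALSE
andvi_sq,dry,-0.018772,0.981403,0.003777,TRUE
dndvi_sq,dry,-0.009814,0.990234,0.003132,TRUE
temp_sq,dry,-0.012278,0.987797,0.005011,TRUE
sl:experience,dry,0.002168,1.002170,0.005965,FALSE
log_sl:experience,dry,-0.035228,0.965386,0.005695,TRUE
andvi:experience,dry,0.033742,1.034317,0.031870,FALSE
dndvi:experience,dry,-0.160548,0.851677,0.051272,TRUE
elev:experience,dry,-0.033265,0.967283,0.009731,TRUE
tri:experience,dry,0.052383,1.053779,0.006479,TRUE
temp:experience,dry,0.031204,1.031696,0.010877,TRUE
sl:group_size,dry,-0.121270,0.885795,0.007104,TRUE
log_sl:group_size,dry,0.102707,1.108167,0.007067,TRUE
andvi:group_size,dry,0.003632,1.003638,0.004126,FALSE
dndvi:group_size,dry,0.004128,1.004136,0.004067,TRUE
elev:group_size,dry,-0.007185,0.992841,0.006904,FALSE
tri:group_size,dry,0.026482,1.026836,0.005851,TRUE
temp:group_size,dry,0.000303,1.000303,0.005580,TRUE
sl,wet,-0.085392,0.918152,0.007023,TRUE
log_sl,wet,0.145373,1.156471,0.007344,TRUE
andvi,wet,0.040974,1.041825,0.012642,TRUE
dndvi,wet,0.034369,1.034966,0.015879,TRUE
elev,wet,-0.028966,0.971450,0.009258,TRUE
tri,wet,0.027761,1.028150,0.005825,TRUE
temp,wet,0.008782,1.008821,0.007739,TRUE
experience,wet,-0.012551,0.987527,0.029001,FALSE
group_size,wet,-0.007034,0.992991,0.005433,TRUE
andvi_sq,wet,-0.010235,0.989817,0.003493,TRUE
dndvi_sq,wet,-0.009695,0.990352,0.004679,TRUE
sl:experience,wet,0.031899,1.032414,0.006149,TRUE
log_sl:experience,wet,-0.032891,0.967644,0.006980,FALSE
andvi:experience,wet,0.013910,1.014007,0.008011,FALSE
dndvi:experience,wet,-0.009679,0.990368,0.013125,FALSE
elev:experience,wet,0.020697,1.020912,0.010874,TRUE
tri:experience,wet,-0.015166,0.984949,0.007235,TRUE
sl:group_size,wet,-0.057897,0.943747,0.007664,TRUE
log_sl:group_size,wet,0.072373,1.075057,0.008066,TRUE
andvi:group_size,wet,0.007308,1.007335,0.006514,TRUE
dndvi:group_size,wet,-0.003953,0.996055,0.005836,TRUE
elev:group_size,wet,-0.014649,0.985458,0.006387,TRUE
tri:group_size,wet,0.016766,1.016908,0.005480,TRUE
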