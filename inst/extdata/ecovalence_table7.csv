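genotype,ecovalence_obs,ecovalence_sim,sigma2_obs,sigma2_sim
Sammaz 54,3612.3,6001.5,555.1,936.6
Sammaz 28,3034.1,1021.8,460.8,123.6
Ife Hybrid 5,839.9,2129.8,102.5,304.5
Ife Hybrid 6,687.2,932.9,77.8,109.1
Early White,2496.1,2419.7,372.9,351.9
Sammaz 32,1881.0,1156.2,272.5,145.6
Sammaz 34,2019.9,2964.9,295.2,440.9
Sammaz 41,2658.8,3665.1,399.5,555.2
M1026-10,1559.7,1699.9,220.2,234.4
M1227-12,2259.1,1706.3,334.2,235.4
IWDC2,7240.0,9775.2,1147.4,1552.8
M0926-8,12593.9,17327.9,2021.5,2785.9
Oba Super 9,3083.2,5999.5,468.8,936.3
Sammaz 11,1405.9,1223.2,194.9,156.5
TZL-COMP4,2349.4,3102.7,348.9,463.4
TZBSR,3170.5,2359.8,483.0,342.0
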