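risk_id,site_id,probability,severity,detectability,exposure,reported_magnitude
SR1,S1,5,9,5,5,0.171
SR2,S1,3,9,5,3,0.062
SR3,S1,7,7,7,7,0.366
SR4,S1,5,9,1,7,0.048
SR5,S1,5,5,7,7,0.187
SR6,S1,3,3,9,5,0.062
SR7,S1,7,5,3,7,0.112
SR8,S1,3,3,3,5,0.020
SR9,S1,1,3,7,5,0.016
SR10,S1,1,3,3,3,0.004
SR11,S1,7,5,7,9,0.336
SR12,S1,3,3,7,3,0.029
SR13,S1,3,3,7,3,0.029
SR14,S1,3,3,7,3,0.029
SR15,S1,5,5,7,3,0.080
SR16,S1,1,1,7,3,0.003
SR17,S1,1,3,9,1,0.004
SR18,S1,5,1,7,5,0.027
SR19,S1,1,1,7,3,0.003
SR20,S1,1,3,7,3,0.009
SR21,S1,1,1,7,1,0.001
SR22,S1,1,1,7,1,0.001
SR23,S1,5,3,5,5,0.057
SR24,S1,3,1,5,5,0.011
SR25,S1,1,3,7,3,0.009
SR26,S1,5,5,7,5,0.133
SR27,S1,3,3,7,3,0.029
SR28,S1,1,3,7,3,0.009
SR29,S1,1,3,7,3,0.009
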