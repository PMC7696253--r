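risk_id,actual,predicted,error,aggregated,band,action,rank
SR1,0.133,0.137,0.004,0.119,Critical,Elimination,3
SR2,0.187,0.187,0.000,0.109,Critical,Elimination,6
SR3,0.261,0.274,0.013,0.122,Critical,Elimination,2
SR4,0.187,0.187,0.000,0.115,Critical,Elimination,4
SR5,0.080,0.080,0.000,0.085,Critical,Elimination,7
SR6,0.029,0.029,0.000,0.047,Critical,Elimination,12
SR7,0.111,0.111,0.000,0.141,Critical,Elimination,1
SR8,0.004,0.004,0.000,0.033,Major,Mitigation,14
SR9,0.029,0.029,0.000,0.030,Major,Mitigation,16
SR10,0.034,0.034,0.000,0.015,Major,Mitigation,24
SR11,0.202,0.125,0.077,0.112,Critical,Elimination,5
SR12,0.062,0.000,0.062,0.084,Negligible,Acceptance,28
SR13,0.037,0.037,0.000,0.053,Major,Mitigation,11
SR14,0.080,0.080,0.000,0.031,Major,Mitigation,15
SR15,0.048,0.048,0.000,0.039,Critical,Elimination,13
SR16,0.016,0.016,0.000,0.007,Minor,Mitigation,27
SR17,0.007,0.000,0.007,0.018,Major,Mitigation,23
SR18,0.133,0.133,0.000,0.082,Critical,Elimination,8
SR19,0.012,0.012,0.000,0.010,Minor,Mitigation,26
SR20,0.080,0.080,0.000,0.064,Critical,Elimination,10
SR21,0.020,0.020,0.000,0.019,Major,Mitigation,21
SR22,0.029,0.029,0.000,0.029,Major,Mitigation,18
SR23,0.034,0.034,0.000,0.030,Major,Mitigation,17
SR24,0.009,0.009,0.000,0.004,Major,Mitigation,22
SR25,0.001,0.001,0.000,0.020,Major,Mitigation,20
SR26,0.048,0.048,0.000,0.080,Critical,Elimination,9
SR27,0.048,0.000,0.048,0.064,Negligible,Acceptance,28
SR28,0.019,0.019,0.000,0.026,Major,Mitigation,19
SR29,0.007,0.007,0.000,0.011,Minor,Mitigation,25
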