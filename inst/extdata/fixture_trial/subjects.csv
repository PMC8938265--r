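subject_id,arm,stratum,death_day,censor_day,kccq_baseline,kccq_day90,off_treatment_day,cov_ntprobnp
T1,treated,de_novo,,90,40,70,,2800
T2,treated,decompensated,,90,30,50,,4100
T3,treated,decompensated,,90,50,54,20,1900
C1,control,de_novo,10,10,35,,,5200
C2,control,decompensated,,90,40,45,,3300
C3,control,decompensated,60,60,45,,35,2600
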