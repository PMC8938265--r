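subject_id,day,kccq_tss,ntprobnp_pg_ml,weight_kg,loop_diuretic_drug,dose_mg,route
T1,3,42,2700,84.0,furosemide,40,iv
T1,5,46,2292.4,83.2,furosemide,40,oral
T1,15,55,2100,82.0,furosemide,80,oral
T1,30,62,1877.3,81.5,furosemide,40,oral
T1,90,70,1500,81.0,furosemide,40,oral
C2,3,41,3400,78.0,torasemide,20,iv
C2,5,41,3233.6,77.8,torasemide,20,oral
C2,15,43,3100,77.2,torasemide,20,oral
C2,30,44,2987.1,77.0,torasemide,20,oral
C2,90,45,2900,76.8,torasemide,20,oral
T2,5,33,4000,90.1,bumetanide,1,iv
T2,30,42,3500,88.9,bumetanide,1,oral
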