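subject_id,diagnosis,sex,age,d4z4_kb,muscle,dev_myhc_count,fibre_count,fibre_size_variation,central_nuclei,fibrosis,nri,necrosis
D3,DM2,F,57,,tibialis_anterior,2,406,2,2,0,0,0
D4,DM2,M,61,,tibialis_anterior,1,678,2,2,1,0,0
D5,DM2,F,54,,tibialis_anterior,1,554,3,1,0,1,0
D9,DM2,F,65,,quadriceps,11,362,2,2,1,1,1
D2,DM2,M,52,,tibialis_anterior,8,247,3,2,1,1,1
D1,DM2,M,62,,tibialis_anterior,10,452,3,3,1,1,0
D6,DM2,M,44,,quadriceps,2,580,3,2,2,1,0
D8,DM2,F,59,,quadriceps,2,243,3,2,1,2,0
D7,DM2,F,64,,quadriceps,9,1245,3,2,3,2,1
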