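subject_id,diagnosis,sex,age,d4z4_kb,muscle,dev_myhc_count,fibre_count,fibre_size_variation,central_nuclei,fibrosis,nri,necrosis
41,FSHD1,F,53,22,tibialis_anterior,2,1173,0,0,0,1,1
39,FSHD1,M,64,33,tibialis_anterior,0,616,1,0,0,1,1
40,FSHD1,F,41,20,tibialis_anterior,1,647,2,0,0,0,0
35,FSHD1,F,55,29,tibialis_anterior,1,428,2,1,0,0,0
45,FSHD1,F,66,17,tibialis_anterior,1,286,2,1,0,0,0
42,FSHD1,M,65,22,tibialis_anterior,2,394,3,0,0,2,1
44,FSHD1,F,50,19,tibialis_anterior,1,1996,3,1,2,1,1
38,FSHD2,F,49,43,tibialis_anterior,4,266,3,2,1,2,1
43,FSHD1,M,68,27,tibialis_anterior,12,388,3,1,1,3,0
37,FSHD1,M,38,28,tibialis_anterior,25,721,3,2,1,3,1
36,FSHD1,M,33,22,tibialis_anterior,50,530,3,2,3,2,1
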