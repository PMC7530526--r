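subject_id,diagnosis,sex,age,d4z4_kb,muscle,dev_myhc_count,fibre_count,fibre_size_variation,central_nuclei,fibrosis,nri,necrosis
20,FSHD1,M,59,32,quadriceps,0,619,1,0,0,0,0
31,FSHD1,F,57,18,quadriceps,0,1498,1,0,0,0,0
32,FSHD1,M,36,33,quadriceps,2,668,1,0,0,0,0
1,FSHD1,M,54,28,quadriceps,3,994,2,0,0,0,0
4,FSHD2,F,56,67,quadriceps,2,137,1,0,0,1,0
5,FSHD1,F,53,31,quadriceps,3,2178,1,0,0,1,0
8,FSHD2,F,69,43,quadriceps,3,412,1,1,0,0,0
10,FSHD1,F,29,12,quadriceps,3,801,1,0,1,0,0
13,FSHD1,F,60,26,quadriceps,0,2079,2,0,0,0,0
14,FSHD1,M,40,29,quadriceps,0,945,2,0,0,0,0
17,FSHD1,M,47,25,quadriceps,0,734,2,0,0,0,0
18,FSHD1,M,56,23,quadriceps,2,1438,2,0,0,0,0
21,FSHD1,F,46,15,quadriceps,6,1725,2,0,0,0,0
22,FSHD1,F,47,27,quadriceps,0,1955,2,0,0,0,0
7,FSHD1,F,47,35,quadriceps,1,766,3,0,0,0,0
19,FSHD1,M,40,28,quadriceps,0,1160,2,0,0,1,0
28,FSHD1,M,25,18,quadriceps,0,588,2,0,1,0,0
6,FSHD1,M,50,13,quadriceps,1,625,3,0,0,1,0
9,FSHD1,F,26,15,quadriceps,1,744,2,1,1,0,0
15,FSHD1,F,47,19,quadriceps,1,1672,2,0,1,1,1
16,FSHD1,M,63,23,quadriceps,1,1341,3,0,1,0,0
27,FSHD1,F,38,28,quadriceps,6,709,1,1,0,2,1
34,FSHD1,M,50,34,quadriceps,5,714,2,1,0,1,0
3,FSHD1,M,56,17,quadriceps,2,836,3,1,1,0,0
11,FSHD1,F,59,10,quadriceps,1,264,3,1,1,0,0
23,FSHD2,M,50,46,quadriceps,1,309,2,1,0,2,1
26,FSHD1,M,65,27,quadriceps,2,405,3,0,0,2,1
24,FSHD1,F,54,24,quadriceps,1,490,2,1,1,2,1
25,FSHD1,F,36,25,quadriceps,2,1679,2,1,2,1,0
33,FSHD1,F,24,16,quadriceps,12,1300,2,1,1,2,1
12,FSHD1_mosaic,M,62,19,quadriceps,3,529,3,1,3,1,0
2,FSHD1,M,75,19,quadriceps,13,862,3,1,3,3,1
29,FSHD1,M,56,20,quadriceps,5,101,3,3,3,1,0
30,FSHD1,M,49,15,quadriceps,3,463,3,2,3,2,1
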