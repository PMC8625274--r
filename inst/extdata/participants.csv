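subject_id,age_years,gender,height_cm,weight_kg
1,29,M,180,77.5
2,24,M,178,80.0
3,24,F,165,61.8
4,24,F,150,50.8
5,26,F,170,57.4
6,24,M,181,60.1
7,23,M,173,84.3
8,23,M,180,65.9
9,24,F,161,58.0
10,24,F,160,51.5
11,25,M,178,67.8
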