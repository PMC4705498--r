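code,group,sex,years_experience,years_pd,years_ehealth
1,technical,female,26,5,26
2,technical,male,20,11,20
3,technical,male,8,7,8
4,technical,male,12,6,12
5,technical,male,7,5,6
6,technical,male,7,5,6
7,technical,male,10,1,8
8,technical,male,10,2,8
9,technical,male,5,4,5
10,technical,male,7,5,6
11,clinical,female,8,4,5
12,clinical,female,12,10,4
13,clinical,male,19,11,5
14,clinical,male,25,25,15
15,clinical,female,26,12,0
16,clinical,female,4,4,2
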