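participant,sex,age,tooth,hvc
1,F,34,11,CM
1,F,34,21,HL
2,M,38,21,HL
3,M,41,21,HL
4,F,53,21,HL
5,F,42,11,CM
6,F,47,11,CL
7,M,44,22,HL
7,M,44,21,HL
8,M,53,11,HL
9,F,42,12,HL
9,F,42,11,HL
9,F,42,21,CL
9,F,42,22,HL
10,F,60,11,HL
10,F,60,12,HL
11,M,55,12,HL
11,M,55,11,HL
12,F,70,11,HL
12,F,70,21,CM
13,F,48,12,HL
14,M,28,11,CM
15,M,72,12,HL
15,M,72,11,HL
15,M,72,21,HL
16,M,47,12,CL
16,M,47,11,CL
16,M,47,21,CL
16,M,47,22,CM
17,M,55,21,CM
18,M,30,12,HL
18,M,30,11,HL
18,M,30,21,HL
19,M,20,12,HL
20,F,42,13,HL
20,F,42,12,HL
20,F,42,11,HM
21,M,32,11,HL
22,M,48,21,CL
23,M,45,11,HL
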