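id,weight,area,educ,diet_class,adequate,stunting,child_age_months,interview_day
1,1,1,0,1,0,1,6,1
2,2,1,0,1,0,0,8,2
3,1,1,1,1,0,1,10,3
4,1,0,0,1,0,0,12,4
5,1,0,1,0,1,0,14,5
6,2,1,0,0,1,0,16,6
7,1,0,0,0,1,0,18,7
8,1,1,1,0,1,0,20,8
9,1,0,1,1,0,0,22,9
10,1,0,0,1,0,1,24,10
11,1,1,1,1,0,0,7,11
12,1,0,1,0,1,0,9,12
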