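"index","name","side","lobe","pair_index","excluded"
1,"epiplastra external contact between each other","medial","anterior",,FALSE
2,"xiphiplastra external contact between each other","medial","posterior",,FALSE
3,"epiplastron medial contact with entoplastron","right","anterior",16,FALSE
4,"entoplastron medial contact with hyoplastron","right","anterior",17,FALSE
5,"hyoplastron medial contact with hypoplastron","right","anterior",18,FALSE
6,"hyoplastron medial contact with hypoplastron","right","posterior",19,FALSE
7,"hypoplastron medial contact with xiphiplastron","right","posterior",20,FALSE
8,"entoplastron contact with epiplastron and hyoplastron","right","anterior",21,FALSE
9,"epiplastron lateral contact with hyoplastron","right","anterior",22,FALSE
10,"axillary notch inflection point","right","anterior",23,FALSE
11,"hyoplastron lateral contact with hypoplastron","right","anterior",24,FALSE
12,"hyoplastron lateral contact with hypoplastron","right","posterior",25,FALSE
13,"inguinal notch inflection point","right","posterior",26,FALSE
14,"hypoplastron lateral contact with xiphiplastron","right","posterior",27,FALSE
15,"xiphiplastron inflection point of external border","right","posterior",28,FALSE
16,"epiplastron medial contact with entoplastron","left","anterior",3,FALSE
17,"entoplastron medial contact with hyoplastron","left","anterior",4,FALSE
18,"hyoplastron medial contact with hypoplastron","left","anterior",5,FALSE
19,"hyoplastron medial contact with hypoplastron","left","posterior",6,FALSE
20,"hypoplastron medial contact with xiphiplastron","left","posterior",7,FALSE
21,"entoplastron contact with epiplastron and hyoplastron","left","anterior",8,FALSE
22,"epiplastron lateral contact with hyoplastron","left","anterior",9,FALSE
23,"axillary notch inflection point","left","anterior",10,FALSE
24,"hyoplastron lateral contact with hypoplastron","left","anterior",11,FALSE
25,"hyoplastron lateral contact with hypoplastron","left","posterior",12,FALSE
26,"inguinal notch inflection point","left","posterior",13,FALSE
27,"hypoplastron lateral contact with xiphiplastron","left","posterior",14,FALSE
28,"xiphiplastron inflection point of external border","left","posterior",15,FALSE
29,"gular medial contact with humeral","right","anterior",39,FALSE
30,"humeral medial contact with pectoral","right","anterior",40,FALSE
31,"pectoral medial contact with abdominal","right","anterior",41,FALSE
32,"abdominal medial contact with femoral","right","posterior",42,FALSE
33,"femoral medial contact with anal","right","posterior",43,FALSE
34,"gular lateral contact with humeral","right","anterior",44,FALSE
35,"humeral lateral contact with pectoral","right","anterior",45,FALSE
36,"pectoral lateral contact with abdominal","right","anterior",46,FALSE
37,"abdominal lateral contact with femoral","right","posterior",47,FALSE
38,"femoral lateral contact with anal","right","posterior",48,FALSE
39,"gular medial contact with humeral","left","anterior",29,FALSE
40,"humeral medial contact with pectoral","left","anterior",30,FALSE
41,"pectoral medial contact with abdominal","left","anterior",31,FALSE
42,"abdominal medial contact with femoral","left","posterior",32,FALSE
43,"femoral medial contact with anal","left","posterior",33,FALSE
44,"gular lateral contact with humeral","left","anterior",34,FALSE
45,"humeral lateral contact with pectoral","left","anterior",35,FALSE
46,"pectoral lateral contact with abdominal","left","anterior",36,FALSE
47,"abdominal lateral contact with femoral","left","posterior",37,FALSE
48,"femoral lateral contact with anal","left","posterior",38,FALSE
49,"peripheral 3 external contact with peripheral 4","right","none",51,TRUE
50,"peripheral 7 external contact with peripheral 8","right","none",52,TRUE
51,"peripheral 3 external contact with peripheral 4","left","none",49,TRUE
52,"peripheral 7 external contact with peripheral 8","left","none",50,TRUE
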