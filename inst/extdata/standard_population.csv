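sex,age_lo,age_hi,weight
f,0,5,2500
f,5,10,2750
f,10,15,2750
f,15,20,2750
f,20,25,3000
f,25,30,3000
f,30,35,3250
f,35,40,3500
f,40,45,3500
f,45,50,3500
f,50,55,3500
f,55,60,3250
f,60,65,3000
f,65,70,2750
f,70,75,2500
f,75,80,2000
f,80,85,1250
f,85,90,750
f,90,95,400
f,95,100,100
m,0,5,2500
m,5,10,2750
m,10,15,2750
m,15,20,2750
m,20,25,3000
m,25,30,3000
m,30,35,3250
m,35,40,3500
m,40,45,3500
m,45,50,3500
m,50,55,3500
m,55,60,3250
m,60,65,3000
m,65,70,2750
m,70,75,2500
m,75,80,2000
m,80,85,1250
m,85,90,750
m,90,95,400
m,95,100,100
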