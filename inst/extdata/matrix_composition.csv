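compound,Mnc,Mcov,Mno
CAT,4.39,5.83,4.16
EPI,10.8,11.3,8.9
PCA,59.0,50.9,63.9
DPn,5.6,5.6,6.3
PLX,0.87,0.94,0.68
PLZ,4.56,5.35,3.17
5CQA,17.42,22.26,17.39
pCQA,1.27,1.50,1.10
TotalFl,1.74,1.82,0.67
EC,NA,0.02,NA
CYA,NA,0.08,NA
Rha,9,7,11
Fuc,5,4,1
Ara,76,71,81
Xyl,37,37,47
Man,15,12,9
Gal,49,45,45
Glc,214,174,254
GalA,148,144,170
MeOH,22,20,25
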