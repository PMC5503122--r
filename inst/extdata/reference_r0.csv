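set,metal,oxidation,spin,ligand,r0,uncertainty,n_sites,cn_validity
brese,Fe,2,none,N,1.86,NA,NA,NA
brese,Fe,2,none,O,1.734,NA,NA,NA
brese,Fe,2,none,F,1.65,NA,NA,NA
brese,Fe,2,none,S,2.16,NA,NA,NA
brese,Fe,2,none,Cl,2.06,NA,NA,NA
brese,Fe,2,none,Br,2.26,NA,NA,NA
brese,Fe,3,none,N,1.86,NA,NA,NA
brese,Fe,3,none,O,1.759,NA,NA,NA
brese,Fe,3,none,F,1.67,NA,NA,NA
brese,Fe,3,none,S,2.16,NA,NA,NA
brese,Fe,3,none,Cl,2.09,NA,NA,NA
brese,Fe,3,none,Br,2.26,NA,NA,NA
brese,Na,1,none,N,1.93,NA,NA,NA
brese,Na,1,none,O,1.80,NA,NA,NA
brese,Na,1,none,F,1.677,NA,NA,NA
brese,Na,1,none,S,2.28,NA,NA,NA
brese,Na,1,none,Cl,2.15,NA,NA,NA
brese,Na,1,none,Br,2.33,NA,NA,NA
brese,Mg,2,none,N,1.85,NA,NA,NA
brese,Mg,2,none,O,1.69,NA,NA,NA
brese,Mg,2,none,F,1.58,NA,NA,NA
brese,Mg,2,none,S,2.18,NA,NA,NA
brese,Mg,2,none,Cl,2.08,NA,NA,NA
brese,Mg,2,none,Br,2.28,NA,NA,NA
brese,K,1,none,N,2.26,NA,NA,NA
brese,K,1,none,O,2.13,NA,NA,NA
brese,K,1,none,F,1.99,NA,NA,NA
brese,K,1,none,S,2.59,NA,NA,NA
brese,K,1,none,Cl,2.52,NA,NA,NA
brese,K,1,none,Br,2.66,NA,NA,NA
brese,Ca,2,none,N,2.14,NA,NA,NA
brese,Ca,2,none,O,1.96,NA,NA,NA
brese,Ca,2,none,F,1.84,NA,NA,NA
brese,Ca,2,none,S,2.45,NA,NA,NA
brese,Ca,2,none,Cl,2.37,NA,NA,NA
brese,Ca,2,none,Br,2.49,NA,NA,NA
brese,Zn,2,none,N,1.77,NA,NA,NA
brese,Zn,2,none,O,1.74,NA,NA,NA
brese,Zn,2,none,F,1.62,NA,NA,NA
brese,Zn,2,none,S,2.09,NA,NA,NA
brese,Zn,2,none,Cl,2.01,NA,NA,NA
brese,Zn,2,none,Br,2.15,NA,NA,NA
liu,Fe,2,none,N,1.769,NA,NA,NA
liu,Fe,2,none,O,1.700,NA,NA,NA
liu,Fe,2,none,S,2.125,NA,NA,NA
liu,Fe,3,none,N,1.815,NA,NA,NA
liu,Fe,3,none,O,1.765,NA,NA,NA
liu,Fe,3,none,S,2.134,NA,NA,NA
csd,Fe,2,LS,N,1.57,0.02,497,NA
csd,Fe,2,HS,N,1.76,0.02,751,NA
csd,Fe,2,none,O,1.70,0.04,1144,NA
csd,Fe,2,none,F,1.67,0.04,34,NA
csd,Fe,2,none,S,2.08,0.09,159,4
csd,Fe,2,none,Cl,2.05,0.03,518,NA
csd,Fe,2,none,Br,2.21,0.02,65,NA
csd,Fe,3,LS,N,1.70,0.02,114,NA
csd,Fe,3,HS,N,1.83,0.03,62,NA
csd,Fe,3,none,O,1.76,0.03,2663,NA
csd,Fe,3,none,F,1.67,0.04,60,NA
csd,Fe,3,none,S,2.10,0.11,68,4
csd,Fe,3,none,Cl,2.09,0.02,1034,NA
csd,Fe,3,none,Br,2.23,0.04,104,NA
csd,Na,1,none,N,1.88,0.08,702,NA
csd,Na,1,none,O,1.75,0.09,2404,NA
csd,Na,1,none,F,1.67,0.05,75,NA
csd,Na,1,none,S,2.23,0.08,126,NA
csd,Na,1,none,Cl,2.16,0.04,87,NA
csd,Na,1,none,Br,2.32,0.06,15,NA
csd,Mg,2,none,N,1.78,0.06,509,NA
csd,Mg,2,none,O,1.67,0.04,1075,NA
csd,Mg,2,none,F,1.64,0.01,9,NA
csd,Mg,2,none,S,2.20,0.04,28,NA
csd,Mg,2,none,Cl,2.11,0.03,90,NA
csd,Mg,2,none,Br,2.26,0.02,66,NA
csd,K,1,none,N,2.22,0.08,950,NA
csd,K,1,none,O,2.07,0.07,2123,NA
csd,K,1,none,F,2.03,0.05,101,NA
csd,K,1,none,S,2.62,0.07,170,NA
csd,K,1,none,Cl,2.49,0.04,107,NA
csd,K,1,none,Br,2.63,0.05,17,NA
csd,Ca,2,none,N,2.07,0.05,316,NA
csd,Ca,2,none,O,1.93,0.04,801,NA
csd,Ca,2,none,F,1.89,0.01,2,NA
csd,Ca,2,none,S,2.42,0.04,15,NA
csd,Ca,2,none,Cl,2.33,0.01,31,NA
csd,Ca,2,none,Br,2.51,0.02,14,NA
csd,Zn,2,none,N,1.75,0.03,9275,NA
csd,Zn,2,none,O,1.69,0.02,8811,NA
csd,Zn,2,none,F,1.64,0.02,18,NA
csd,Zn,2,none,S,2.09,0.02,1330,NA
csd,Zn,2,none,Cl,2.01,0.01,20549,NA
csd,Zn,2,none,Br,2.14,0.01,403,NA
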