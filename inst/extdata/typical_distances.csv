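metal,oxidation,spin,ligand,cn,s_effective,r0,distance,allowlisted
Na,1,none,N,6,1,1.88,2.54,FALSE
Na,1,none,O,6,1,1.75,2.41,FALSE
Na,1,none,F,6,1,1.67,2.33,FALSE
Na,1,none,S,6,1,2.23,2.89,FALSE
Na,1,none,Cl,6,1,2.16,2.82,FALSE
Na,1,none,Br,6,1,2.32,2.98,FALSE
Mg,2,none,N,6,2,1.78,2.19,FALSE
Mg,2,none,O,6,2,1.67,2.08,FALSE
Mg,2,none,F,6,2,1.64,2.05,FALSE
Mg,2,none,S,6,2,2.20,2.61,FALSE
Mg,2,none,Cl,6,2,2.11,2.52,FALSE
Mg,2,none,Br,6,2,2.26,2.67,FALSE
K,1,none,N,6,1,2.22,2.88,FALSE
K,1,none,O,6,1,2.07,2.73,FALSE
K,1,none,F,6,1,2.03,2.69,FALSE
K,1,none,S,6,1,2.62,3.28,FALSE
K,1,none,Cl,6,1,2.49,3.15,FALSE
K,1,none,Br,6,1,2.63,3.29,FALSE
Ca,2,none,N,6,2,2.07,2.48,FALSE
Ca,2,none,O,6,2,1.93,2.34,FALSE
Ca,2,none,F,6,2,1.89,2.30,FALSE
Ca,2,none,S,6,2,2.42,2.83,FALSE
Ca,2,none,Cl,6,2,2.33,2.74,FALSE
Ca,2,none,Br,6,2,2.51,2.92,FALSE
Zn,2,none,N,4,2,1.75,2.01,FALSE
Zn,2,none,O,4,2,1.69,1.95,FALSE
Zn,2,none,F,4,2,1.64,1.90,FALSE
Zn,2,none,S,4,2,2.09,2.35,FALSE
Zn,2,none,Cl,4,2,2.01,2.27,FALSE
Zn,2,none,Br,4,2,2.14,2.40,FALSE
Fe,2,LS,N,6,2,1.57,1.98,FALSE
Fe,2,HS,N,6,2,1.76,2.17,FALSE
Fe,2,none,O,6,2,1.70,2.11,FALSE
Fe,2,none,F,6,2,1.67,2.08,FALSE
Fe,2,none,S,4,2,2.08,2.33,TRUE
Fe,2,none,Cl,6,2,2.05,2.46,FALSE
Fe,2,none,Br,6,2,2.21,2.62,FALSE
Fe,3,LS,N,6,2,1.70,2.11,FALSE
Fe,3,HS,N,6,2,1.83,2.24,FALSE
Fe,3,none,O,6,2,1.76,2.17,FALSE
Fe,3,none,F,6,2,1.67,2.08,FALSE
Fe,3,none,S,4,2,2.10,2.35,TRUE
Fe,3,none,Cl,6,2,2.09,2.50,FALSE
Fe,3,none,Br,6,2,2.23,2.64,FALSE
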