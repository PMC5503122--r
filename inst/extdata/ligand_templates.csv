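template,charge,donor_element
aqua,0,O
hydroxo,-1,O
oxo,-2,O
carboxylato,-1,O
acetato,-1,O
phenolato,-1,O
nitrato,-1,O
sulfato,-2,O
alkoxo,-1,O
chloro,-1,Cl
bromo,-1,Br
fluoro,-1,F
ammine,0,N
amine,0,N
pyridyl,0,N
imidazolyl,0,N
triazolyl,0,N
azido,-1,N
nitro,-1,N
cyanato,-1,N
thiolato,-1,S
thioether,0,S
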