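element,line,energy_kev,provenance
P,Ka1,2.014,standard-table
P,Kb1,2.139,standard-table
K,Ka1,3.31,reported
K,Kb1,3.590,standard-table
Ca,Ka1,3.692,reported
Ca,Kb1,4.01,reported
Ti,Ka1,4.51,reported
Ti,Kb1,4.932,standard-table
V,Ka1,4.95,reported
V,Kb1,5.427,standard-table
Cr,Ka1,5.41,reported
Cr,Kb1,5.947,standard-table
Mn,Ka1,5.90,reported
Mn,Kb1,6.490,standard-table
Fe,Ka1,6.405,reported
Fe,Kb1,7.06,reported
Co,Ka1,6.930,standard-table
Co,Kb1,7.65,reported
Ni,Ka1,7.48,reported
Ni,Kb1,8.265,standard-table
Cu,Ka1,8.05,reported
Cu,Kb1,8.905,standard-table
Zn,Ka1,8.64,reported
Zn,Kb1,9.57,reported
Ga,Ka1,9.25,reported
Ga,Kb1,10.27,reported
Ge,Ka1,9.89,reported
Ge,Kb1,10.982,standard-table
As,Ka1,10.54,reported
As,Kb1,11.73,reported
Se,Ka1,11.20,reported
Se,Kb1,12.496,standard-table
Br,Ka1,11.92,reported
Br,Kb1,13.292,standard-table
Kr,Ka1,12.65,reported
Kr,Kb1,14.112,standard-table
Rb,Ka1,13.40,reported
Rb,Kb1,14.961,standard-table
Sr,Ka1,14.17,reported
Sr,Kb1,15.84,reported
Y,Ka1,14.958,reported
Y,Kb1,16.738,standard-table
Ce,La1,4.84,reported
Nd,La1,5.23,reported
Th,La1,12.97,reported
U,La1,13.615,standard-table
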