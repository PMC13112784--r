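# label priority, highest first (default order)
Fe_A
Zn_A
Ca_A
Mg_A
Ni_A
Na_A
K_A
Cl_A
HB_OH_O
HB_NH_O
HB_OH_N
HB_NH_N
Ele_OH_O
Ele_NH_O
Ele_OH_N
Ele_NH_N
OMulPol
Dipo
S_O
S_N
S_S
CH_PI
NH_PI
OH_PI
SH_PI
PI_PI
S_PI
CH_O
CH_N
CH_S
OH_S
NH_S
SH_O
SH_N
SH_S
vdW
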