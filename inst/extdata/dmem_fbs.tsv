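metabolite	concentration_mM
glc_e	25
o2_e	100
glu_e	0.5
cys_e	0.2
gly_e	0.4
nh4_e	0.5
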