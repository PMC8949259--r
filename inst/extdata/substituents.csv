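# Substituent library for DAP modification: the 12 groups named in the design
# discussion plus COOCH3 and CH=CH2, which appear only in derivative names.
# fragment: SMILES written so it can be appended at an open valence.
name,fragment,note
F,F,
CL,Cl,source spelling CL
Br,Br,
SH,S,
CH3,C,
CH2CH3,CC,
CH2CH2CH3,CCC,
C6H5,c2ccccc2,
CH2C6H5,Cc2ccccc2,
NO2,[N+](=O)[O-],
CH2NO2,C[N+](=O)[O-],
OCH3,OC,
COOCH3,C(=O)OC,named only in derivative tables
CH=CH2,C=C,named only in derivative tables
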