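# Curated SMILES for the 13 PAEs. Branched-isomer expansions marked "editorial"
# are inferred from the abbreviation; the source lists abbreviations only.
compound,name,smiles,note
DAP,diallyl phthalate,C(=C)COC(=O)c1ccccc1C(=O)OCC=C,
DEP,diethyl phthalate,CCOC(=O)c1ccccc1C(=O)OCC,
DHP,dihexyl phthalate,CCCCCCOC(=O)c1ccccc1C(=O)OCCCCCC,
DIBP,diisobutyl phthalate,CC(C)COC(=O)c1ccccc1C(=O)OCC(C)C,
DIHP,diisoheptyl phthalate,CC(C)CCCCOC(=O)c1ccccc1C(=O)OCCCCC(C)C,editorial: 5-methylhexyl isomer
DIHXP,diisohexyl phthalate,CC(C)CCCOC(=O)c1ccccc1C(=O)OCCCC(C)C,editorial: 4-methylpentyl isomer
DIPP,diisopentyl phthalate,CC(C)CCOC(=O)c1ccccc1C(=O)OCCC(C)C,editorial: 3-methylbutyl isomer
DIPRP,diisopropyl phthalate,CC(C)OC(=O)c1ccccc1C(=O)OC(C)C,
DMP,dimethyl phthalate,COC(=O)c1ccccc1C(=O)OC,
DPP,dipentyl phthalate,CCCCCOC(=O)c1ccccc1C(=O)OCCCCC,
DPRP,dipropyl phthalate,CCCOC(=O)c1ccccc1C(=O)OCCC,
DTDP,ditridecyl phthalate,CCCCCCCCCCCCCOC(=O)c1ccccc1C(=O)OCCCCCCCCCCCCC,editorial: linear tridecyl isomer
DMEP,bis(2-methoxyethyl) phthalate,COCCOC(=O)c1ccccc1C(=O)OCCOC,
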