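# Normalized indicators and comprehensive effect value I for the 13 PAEs.
# q_permittivity: printed normalized insulation indicator (supplied data; not derivable
# from the raw column by either min-max formula). q_toxicity: normalized LC50 on the
# x1000 display scale. q_bcf: normalized logBCF (negative indicator). set: training (a),
# test (b) or both (ab) membership in the QSAR split.
compound,q_permittivity,q_toxicity,q_bcf,I,set
DAP,0.81,42.882,0.60,0.52,a
DEP,1.00,100.467,0.75,0.66,a
DHP,0.67,0.765,0.32,0.33,a
DIBP,0.82,10.924,0.44,0.44,a
DIHP,0.84,0.225,0.19,0.31,b
DIHXP,0.96,0.934,0.18,0.33,a
DIPP,0.96,3.206,0.18,0.33,b
DIPRP,0.79,36.800,0.68,0.56,a
DMP,1.00,328.865,1.00,0.85,ab
DPP,0.65,2.634,0.26,0.30,a
DPRP,0.91,30.202,0.54,0.52,a
DTDP,0.75,0.000,0.59,0.49,a
DMEP,0.96,1000,0.74,0.85,b
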