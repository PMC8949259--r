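# Raw endpoint values for 13 phthalic acid esters (PAEs).
# permittivity: relative permittivity (F/m); lc50: fish LC50 (mg/L); logbcf: log bioconcentration factor.
compound,permittivity,lc50,logbcf
DAP,1.00184,5.323,1.798
DEP,1.00109,12.471,1.264
DHP,1.01600,0.095,2.793
DIBP,1.00560,1.356,2.379
DIHP,1.00023,0.028,3.255
DIHXP,1.00115,0.116,3.908
DIPP,1.00016,0.398,3.260
DIPRP,1.00005,4.568,1.534
DMP,1.00310,40.822,0.402
DPP,1.00459,0.327,2.988
DPRP,1.00214,3.749,2.001
DTDP,1.04921,0.00001,1.825
DMEP,1.00087,124.130,1.330
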