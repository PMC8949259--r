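# MM-PBSA binding free energies (kJ/mol) of DAP and three derivatives with the
# carboxylesterase receptor 5UOH at 0 V and 5 V applied field, with percent
# changes relative to DAP at the same field strength.
compound,dg_0v,change_0v,dg_5v,change_5v
DAP,-80.027,NA,-35.095,NA
DAP-1-NO2-2-CH2C6H5,-91.797,-14.71,-22.167,36.84
DAP-1-NO2-2-CH2CH2CH3,-136.126,-70.10,-137.160,-290.82
DAP-1-NO2-2-OCH3,-117.931,-47.36,-73.976,-110.79
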