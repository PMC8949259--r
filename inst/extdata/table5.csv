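# Docking scoring-function values of DAP and the four shortlisted derivatives
# against the insulation (5UOH), toxicity (6XXK) and bioconcentration (4R20)
# receptors, with percent changes relative to DAP.
compound,score_insulation,change_insulation,score_toxicity,change_toxicity,score_bcf,change_bcf
DAP,69.56,NA,70.49,NA,65.46,NA
DAP-1-NO2-2-C6H5,84.33,21.23,73.12,3.73,58.44,-10.72
DAP-1-NO2-2-CH2C6H5,100.31,44.20,88.95,26.19,64.83,-0.95
DAP-1-NO2-2-CH2CH2CH3,79.05,13.65,80.06,13.58,62.49,-4.54
DAP-1-NO2-2-OCH3,87.28,25.47,77.89,10.49,62.56,-4.43
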