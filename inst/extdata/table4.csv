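# Predicted effect values of DAP and 30 derivatives from the comprehensive and
# single-effect QSAR models, with percent changes relative to DAP. The row
# DAP-1-NO2-2-CH2CH2CH3 was printed without a name; its label is an editorial
# inference (the only scored derivative absent from the printed names).
compound,pred_comprehensive,change_comprehensive,pred_insulation,change_insulation,pred_toxicity,change_toxicity,pred_enrichment,change_enrichment
DAP,0.61,NA,1.002,NA,0.73,NA,1.80,NA
DAP-1-Br,0.65,6.23,1.002,0.00,0.87,18.49,1.64,-8.62
DAP-1-CH2C6H5,0.71,17.05,1.003,0.10,0.92,26.30,1.47,-18.19
DAP-1-CH2NO2,0.87,43.11,1.002,0.00,2.28,212.47,1.01,-43.99
DAP-1-F,0.72,18.03,1.002,0.00,1.11,52.05,1.35,-24.69
DAP-1-NO2,0.73,19.02,1.002,0.00,2.01,174.79,1.48,-17.58
DAP-1-SH,0.73,19.18,1.002,0.00,1.13,54.52,1.36,-24.36
DAP-2-Br,0.75,22.62,1.004,0.20,1.22,66.71,1.28,-28.92
DAP-2-CH2NO2,0.97,59.34,1.004,0.20,2.27,210.41,0.16,-90.99
DAP-2-CL,0.67,9.51,1.002,0.00,0.81,10.68,1.78,-0.78
DAP-2-COOCH3,0.73,19.34,1.004,0.20,0.83,14.11,1.21,-32.93
DAP-2-F,0.73,19.84,1.002,0.00,1.00,36.85,1.39,-22.69
DAP-2-NO2,0.97,58.85,1.003,0.10,1.94,165.89,0.18,-89.82
DAP-2-SH,0.69,13.77,1.002,0.00,0.94,28.63,1.60,-10.79
DAP-1-NO2-2-C6H5,0.77,26.89,1.003,0.10,1.06,44.66,1.35,-25.08
DAP-1-NO2-2-CH2C6H5,0.85,39.34,1.003,0.10,1.06,127.81,1.18,-34.26
DAP-1-NO2-2-CH2CH2CH3,0.79,29.51,1.005,0.30,0.91,24.52,0.83,-53.78
DAP-1-NO2-2-CH2CH3,0.82,34.43,1.004,0.20,1.88,157.95,1.48,-17.58
DAP-1-NO2-2-CH2NO2,1.10,79.84,1.004,0.20,2.55,249.45,1.32,-26.36
DAP-1-NO2-2-CH3,0.79,30.16,1.005,0.30,0.92,26.30,0.83,-53.84
DAP-1-NO2-2-CH=CH2,0.89,45.57,1.005,0.30,2.03,177.81,0.70,-61.29
DAP-1-NO2-2-CL,0.87,42.46,1.003,0.10,1.23,68.08,1.29,-28.31
DAP-1-NO2-2-COOCH3,1.07,74.92,1.002,0.00,0.93,27.26,1.35,-25.08
DAP-1-NO2-2-F,1.05,72.46,1.002,0.00,2.04,178.90,0.72,-59.73
DAP-1-NO2-2-NO2,1.31,114.43,1.003,0.10,3.20,338.22,0.76,-57.68
DAP-1-NO2-2-OCH3,0.84,37.21,1.006,0.40,1.83,150.96,1.40,-22.08
DAP-2-CH=CH2-1-CH2NO2,0.83,36.39,1.003,0.10,0.95,30.41,0.90,-50.06
DAP-2-CH=CH2-1-CH3,0.69,12.46,1.004,0.20,0.90,23.70,1.37,-24.03
DAP-2-CH=CH2-1-NO2,0.88,44.26,1.006,0.40,1.67,128.49,1.17,-35.15
DAP-2-CH=CH2-1-OCH3,0.74,21.97,1.003,0.10,0.94,28.08,1.39,-22.53
DAP-2-CH=CH2-1-SH,0.76,24.92,1.002,0.00,0.84,14.38,1.46,-18.85
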