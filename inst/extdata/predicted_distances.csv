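species,mean_iwl,sqrt_wl,lmm_median_m,ballistic_m
Dipterocarpus humeratus,9.29,326.37,4.25,21.93
Dipterocarpus kerrii,8.93,346.34,3.90,20.54
Hopea beccariana,26.39,189.54,5.30,40.45
Shorea acuminatissima,17.37,231.89,4.13,32.07
Shorea argentifolia,44.60,147.71,7.90,54.53
Shorea beccariana,21.55,207.50,5.86,36.42
Shorea falciferoides,24.85,199.76,5.31,38.05
Shorea gibbosa,11.53,292.07,3.08,24.78
Shorea macroptera,39.83,162.65,6.70,48.50
Shorea mexistopteryx,16.49,242.07,5.48,30.55
Shorea seminis,1.97,724.03,2.27,9.41
Shorea smithiana,20.95,212.99,5.18,35.34
Shorea xanthophylla,0.00,0.00,1.76,NA
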