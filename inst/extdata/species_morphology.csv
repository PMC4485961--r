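species,genus_rule,n_fruit,mean_mass_g,se_mass_g,mean_iwl_cm2_per_g,se_iwl_cm2_per_g,min_dist_m,max_dist_m,median_dist_m,p90_dist_m
Dipterocarpus humeratus,two_winged,59,19.85,1.097,9.29,0.27,0.86,10.86,3.84,7.94
Dipterocarpus kerrii,two_winged,75,6.04,0.267,8.93,0.47,0.83,10.94,4.00,8.14
Hopea beccariana,two_winged,38,0.16,0.004,26.39,0.83,1.30,19.90,3.96,11.26
Shorea acuminatissima,shorea_five_winged,60,0.76,0.023,17.37,0.75,1.00,9.65,3.40,6.75
Shorea argentifolia,shorea_five_winged,55,0.68,0.022,44.60,1.86,1.40,39.54,8.20,15.58
Shorea beccariana,shorea_five_winged,51,3.97,0.083,21.55,0.45,0.42,17.82,6.57,12.20
Shorea falciferoides,shorea_five_winged,61,1.64,0.094,24.85,1.03,1.11,16.33,5.20,10.61
Shorea gibbosa,shorea_five_winged,60,1.04,0.038,11.53,0.58,0.94,7.45,2.62,3.95
Shorea macroptera,shorea_five_winged,54,2.01,0.121,39.83,1.98,1.22,19.41,7.01,12.57
Shorea mexistopteryx,shorea_five_winged,48,11.79,0.536,16.49,0.73,0.94,22.73,5.42,10.76
Shorea seminis,shorea_five_winged,61,1.94,0.116,1.97,0.14,0.76,6.33,1.99,4.13
Shorea smithiana,shorea_five_winged,61,2.64,0.113,20.95,0.65,0.86,20.71,4.84,12.00
Shorea xanthophylla,wingless,45,2.48,0.235,0.00,0.00,0.32,8.26,1.84,4.52
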