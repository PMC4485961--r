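parameter,estimate,ci_lower,ci_upper,approx_p
beta0,0.517,0.377,0.817,0.001
beta1,0.186,0.0759,0.237,0.001
beta2,-0.036,-0.231,0.171,0.816
beta3,0.191,0.115,0.259,0.001
sigma_resid,0.558,0.530,0.591,NA
sigma_species,0.154,0.144,0.235,NA
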