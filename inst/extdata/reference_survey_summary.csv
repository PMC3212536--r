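survey,samples,effort_km,n_obs,cv_encounter_pct,esw_m,cv_density_pct
1995,51,280,460,18.63,2.01,19.07
2006,51,280,286,28.08,2.40,28.70
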