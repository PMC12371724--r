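# Measured mean microparticle diameters and PDI for 17.5 kDa PLA
# (2 wt % rubrene in solids) across core concentrations and delay times,
# batch means of N = 3 independent syntheses.
c_core_mg_per_mL,delay_time_ms,diameter_um,pdi,sd_um
40,30,1.59,0.28,0.01
40,60,1.86,0.12,0.07
40,90,2.24,0.15,0.05
60,30,1.92,0.11,0.09
60,60,2.24,0.17,0.09
60,90,2.57,0.12,0.15
80,30,2.01,0.29,0.20
80,60,2.36,0.27,0.17
80,90,2.87,0.34,0.12
100,30,2.86,0.17,0.11
100,60,2.88,0.24,0.33
100,90,2.98,0.39,0.35
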