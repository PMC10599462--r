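# Apparent pseudo-first-order Michaelis-Menten parameters for RlGabD
# (SLA dehydrogenase, Rhizobium leguminosarum SRDI565).
# The co-substrate was held at 0.25 mM while the varied substrate was
# titrated below the 0.25 mM substrate-inhibition onset.
# Units: KM mM, kcat s^-1, efficiency mM^-1 s^-1; _se columns are standard errors.
varied_substrate,fixed_substrate,KM_mM,KM_se,kcat_s,kcat_se,efficiency_mM_s,efficiency_se
NAD+,D-SLA,0.081,0.019,17.7,3.2,210,63
NADP+,D-SLA,0.017,0.0041,4.1,0.8,240,73
D-SLA,NAD+,0.13,0.04,17.8,7.0,137,72
D-SLA,NADP+,0.16,0.035,4.7,1.1,30,9.4
GAP,NAD+,0.29,0.031,0.73,0.20,4.2,1.2
GAP,NADP+,0.17,0.028,3.0,0.4,10.5,2.3
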