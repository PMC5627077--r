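response,term,p_value,note
polarization,familiarity,0.007,
polarization,time,0.057,
polarization,familiarity:time,0.096,
speed,familiarity,0.023,
speed,time,0.0005,printed as <0.001; any encoding <= 0.001 gives the same BH decision
speed,familiarity:time,0.021,
nnd,familiarity,0.164,
nnd,time,0.035,
nnd,familiarity:time,0.235,
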