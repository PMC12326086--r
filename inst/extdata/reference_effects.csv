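kind,response,reference_level,term,value
effect,flap_frequency,open,urban,-0.10
effect,flap_frequency,open,wooded,0.03
effect,flap_frequency,wooded,urban,-0.12
effect,flight_speed,open,urban,0.69
effect,flight_speed,open,wooded,-0.67
effect,flight_speed,wooded,urban,1.36
mean,flap_frequency,,overall,6.93
mean,flight_speed,,overall,17.92
design,,,n_flocks,3
design,,,birds_flock_L,6
design,,,birds_flock_N,10
design,,,birds_flock_R,8
design,,,flights_per_flock,15
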