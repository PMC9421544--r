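variable	apd_mean	apd_sd	apd_n	hc_mean	hc_sd	hc_n	printed_t	printed_p
age_years	10.92	1.55	28	11.91	1.39	29	2.546	0.014
mean_fd_mm	0.10	0.03	28	0.11	0.04	29	0.962	0.340
total_advantage	0.53	1.04	26	0.47	0.98	28	-0.216	0.830
spatial_advantage	-0.25	1.56	26	0.25	1.06	28	1.398	0.168
talker_advantage	-0.76	0.98	26	-0.25	0.82	28	2.052	0.045
high_cue	0.28	1.08	26	0.48	0.89	28	0.746	0.459
low_cue	-0.35	1.12	26	0.07	0.98	28	1.507	0.138
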