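variable	apd_level1	apd_level2	hc_level1	hc_level2	printed_stat	printed_p
gender_male_female	13	15	14	15	0.020	0.889
handedness_right_left	23	5	26	2	1.631	0.202
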