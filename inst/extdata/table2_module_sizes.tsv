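module	apd_nodes	hc_nodes
default_mode_ventral_attention	86	90
somatomotor	50	38
limbic	76	75
visual	60	62
frontoparietal_dorsal_attention	61	68
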