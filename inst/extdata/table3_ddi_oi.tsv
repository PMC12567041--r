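study	type	cmax_obs	cmax_sim	cmax_rpo_printed	auc_obs	auc_sim	auc_rpo_printed
clarithromycin	ddi_victim	1.19	1.05	0.882	1.36	1.32	0.971
itraconazole	ddi_victim	1.04	1.05	1.01	1.04	1.24	1.19
rifampicin	ddi_victim	1.09	0.838	0.769	0.851	0.566	0.665
imatinib	ddi_victim	1.59	1.15	0.723	2.08	1.99	0.957
midazolam	ddi_perpetrator	1.11	1.18	1.06	1.28	1.23	0.961
warfarin	ddi_perpetrator	1.08	1.03	0.954	1.41	1.40	0.993
repaglinide	ddi_perpetrator	1.14	1.07	0.939	1.08	1.10	1.02
mild_hi	oi	1.26	0.966	0.767	1.22	1.11	0.910
moderate_hi	oi	0.983	0.908	0.924	1.03	1.32	1.28
severe_hi	oi	1.29	0.776	0.602	1.66	1.28	0.771
severe_ri	oi	1.08	1.14	1.06	1.56	1.44	0.923
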