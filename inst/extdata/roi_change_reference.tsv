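stage	region	group	mean	sem	ci_lo	ci_hi	reported_specific
fast	R_AIC	LRN	-0.05	0.03	-0.10	0.01	FALSE
fast	R_AIC	SMP	0.10	0.03	0.04	0.16	FALSE
fast	R_SPC	LRN	0.06	0.03	-0.01	0.12	FALSE
fast	R_SPC	SMP	-0.12	0.03	-0.19	-0.04	FALSE
slow	R_AIC	LRN	0.02	0.03	-0.04	0.08	FALSE
slow	R_AIC	SMP	-0.13	0.02	-0.17	-0.10	FALSE
retention	R_Putamen	LRN	-0.02	0.02	-0.06	0.03	FALSE
retention	R_Putamen	SMP	0.12	0.03	0.06	0.19	FALSE
overall	R_SMA	LRN	-0.10	0.02	-0.14	-0.06	TRUE
overall	R_SMA	SMP	0.03	0.02	-0.02	0.08	TRUE
overall	R_PO	LRN	-0.05	0.02	-0.10	-0.00	FALSE
overall	R_PO	SMP	0.09	0.03	0.03	0.16	FALSE
overall	L_SPC	LRN	0.06	0.02	0.02	0.11	FALSE
overall	L_SPC	SMP	-0.12	0.03	-0.19	-0.06	FALSE
overall	R_SPC	LRN	0.05	0.03	-0.01	0.12	FALSE
overall	R_SPC	SMP	-0.13	0.04	-0.21	-0.04	FALSE
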