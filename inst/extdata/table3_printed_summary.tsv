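phase	model	rmse	r2	adj_r2	f	f_p	correlation
chronic	GP	2.24	0.96	0.95	230	1.02e-07	0.9810
chronic	ERD	8.15	0.61	0.57	14.5	0.00415	0.7857
chronic	multimodal	0.13	0.99	0.99	6.78e+04	9.24e-19	0.9999
early_chronic	GP	15.1	0.70	0.67	18.8	0.00248	0.8378
early_chronic	ERD	14.5	0.74	0.71	22.7	0.00142	0.8599
early_chronic	multimodal	4.85	0.95	0.94	164	1.3e-06	0.9765
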