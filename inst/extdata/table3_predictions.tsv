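phase	model	subject	actual	predicted
chronic	GP	S1	31	30.34
chronic	GP	S2	56	54.23
chronic	GP	S3	44	44.16
chronic	GP	S4	52	51.73
chronic	GP	S5	32	32.58
chronic	GP	S6	40	42.85
chronic	GP	S7	54	52.79
chronic	GP	S8	48	48.74
chronic	GP	S9	45	44.82
chronic	GP	S10	59	64.99
chronic	GP	S11	63	63.44
chronic	ERD	S1	31	46.07
chronic	ERD	S2	56	55.46
chronic	ERD	S3	44	48.66
chronic	ERD	S4	52	55.16
chronic	ERD	S5	32	21.08
chronic	ERD	S6	40	34.44
chronic	ERD	S7	54	54.36
chronic	ERD	S8	48	48.35
chronic	ERD	S9	45	59.28
chronic	ERD	S10	59	55.21
chronic	ERD	S11	63	66.70
chronic	multimodal	S1	31	31.45
chronic	multimodal	S2	56	56.02
chronic	multimodal	S3	44	44.09
chronic	multimodal	S4	52	51.96
chronic	multimodal	S5	32	32.03
chronic	multimodal	S6	40	39.98
chronic	multimodal	S7	54	54.01
chronic	multimodal	S8	48	47.99
chronic	multimodal	S9	45	45.04
chronic	multimodal	S10	59	59.14
chronic	multimodal	S11	63	62.99
early_chronic	GP	S1	51	41.60
early_chronic	GP	S2	66	101.50
early_chronic	GP	S3	66	59.05
early_chronic	GP	S4	36	25.57
early_chronic	GP	S5	61	67.12
early_chronic	GP	S6	55	71.09
early_chronic	GP	S7	21	18.49
early_chronic	GP	S8	46	62.93
early_chronic	GP	S9	14	21.78
early_chronic	GP	S10	66	62.88
early_chronic	ERD	S1	51	50.35
early_chronic	ERD	S2	66	110.40
early_chronic	ERD	S3	66	61.33
early_chronic	ERD	S4	36	35.85
early_chronic	ERD	S5	61	61.06
early_chronic	ERD	S6	55	54.89
early_chronic	ERD	S7	21	20.73
early_chronic	ERD	S8	46	46.52
early_chronic	ERD	S9	14	14.14
early_chronic	ERD	S10	66	65.71
early_chronic	multimodal	S1	51	44.48
early_chronic	multimodal	S2	66	73.95
early_chronic	multimodal	S3	66	75.53
early_chronic	multimodal	S4	36	39.70
early_chronic	multimodal	S5	61	60.64
early_chronic	multimodal	S6	55	55.40
early_chronic	multimodal	S7	21	22.59
early_chronic	multimodal	S8	46	42.28
early_chronic	multimodal	S9	14	12.73
early_chronic	multimodal	S10	66	68.59
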