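phase	column	statistic	value
chronic	age	mean	52.82
chronic	age	sd	5.67
chronic	months_after_onset	mean	50.06
chronic	months_after_onset	sd	15.36
chronic	ul_fma	mean	47.64
chronic	ul_fma	sd	10.46
chronic	gs_palm	mean	3.28
chronic	gs_palm	sd	1.73
chronic	gs_pinch	mean	2.76
chronic	gs_pinch	sd	2.05
early_chronic	age	mean	56.3
early_chronic	age	sd	10.5
early_chronic	months_after_onset	mean	3.32
early_chronic	months_after_onset	sd	0.31
early_chronic	ul_fma	mean	48.20
early_chronic	ul_fma	sd	18.95
early_chronic	gs_palm	mean	1.79
early_chronic	gs_palm	sd	1.83
early_chronic	gs_pinch	mean	4.01
early_chronic	gs_pinch	sd	3.54
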