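corpus	level	mode	precision	recall	f_score
training	mention	lenient	0.82	0.73	0.77
training	mention	strict	0.67	0.59	0.63
development	mention	lenient	0.90	0.82	0.86
development	mention	strict	0.69	0.64	0.66
genome_biology	mention	lenient	0.93	0.89	0.91
genome_biology	mention	strict	0.86	0.82	0.84
evaluation	mention	lenient	0.58	0.68	0.63
evaluation	mention	strict	0.49	0.57	0.53
training	document	lenient	0.75	0.70	0.72
training	document	strict	0.44	0.52	0.48
development	document	lenient	0.81	0.74	0.77
development	document	strict	0.46	0.55	0.51
genome_biology	document	lenient	0.82	0.74	0.78
genome_biology	document	strict	0.62	0.65	0.64
evaluation	document	lenient	0.65	0.60	0.63
evaluation	document	strict	0.40	0.44	0.42
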