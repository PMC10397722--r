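# Published weighted metrics of the cross-species tumor classifier study.
# cohort: human = TCGA-derived test split, canine = canine evaluation cohort.
# precision/recall are the printed weighted percentages (as fractions),
# f1_printed is the printed 3-decimal weighted F1, n_samples the cohort size.
target_id	model	cohort	note	precision	recall	f1_printed	accuracy	n_samples
t1	cCNN-17-PC	human		0.962	0.961	0.961	0.962	9025
t2	cCNN-18-PC	human		0.966	0.964	0.965	0.965	9199
t3	cCNN-17-PC	canine		1.000	0.758	0.862	0.758	95
t4	cCNN-18-PC	canine	grade_collapsed	1.000	0.800	0.889	0.800	95
t5	cCNN-18-PC	canine	grade_resolved	0.613	0.484	0.541	0.484	95
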