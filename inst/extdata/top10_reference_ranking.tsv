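ranking	trimmer	aligner	counter	normalization	median_precision	median_accuracy	overall
1	Trimmomatic	RUM	HTSeq_Union	TMM	68.5	56	249
2	Trimmomatic	RUM	HTSeq_Inter	TMM	68.5	57.75	252.5
3	BBDuk	RUM	HTSeq_Union	TMM	70	56.5	253
4	BBDuk	STAR	HTSeq_Union	TMM	68	62	260
5	Cutadapt	TopHat2	HTSeq_Union	TMM	62.5	67.75	260.5
6	BBDuk	TopHat2	HTSeq_Union	TMM	63.5	68	263
7	BBDuk	HiSat2	HTSeq_Union	TMM	63.5	69.25	265.5
8	BBDuk	TopHat2	HTSeq_Inter	TMM	62.5	70.5	266
9	Trimmomatic	STAR	HTSeq_Union	TMM	69	64.75	267.5
10	Trimmomatic	STAR	HTSeq_Inter	TMM	63.5	71	269
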