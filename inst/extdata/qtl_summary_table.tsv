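qtl	chrom	panel	lod	peak_cm	ci_lo_cm	ci_hi_cm	peak_mb	ci_lo_mb	ci_hi_mb	n_genes	pct_h2	centromeric
Q1	2L	pA	9.9	53.3	53.1	53.6	18.74	18.22	19.26	123	5.5	TRUE
Q1	2L	pB	14.0	53.2	52.8	53.3	18.52	17.65	18.72	81	7.7	TRUE
Q2	2R	pA	27.2	63.6	63.3	63.8	7.07	6.90	7.16	36	14.4	FALSE
Q2	2R	pB	10.3	63.6	62.9	64.3	7.06	6.68	7.43	122	5.7	FALSE
Q3	2R	pA	11.3	66.1	65.8	66.3	8.36	8.21	8.49	65	6.3	FALSE
Q3	2R	pB	10.6	66.3	66.2	66.8	8.49	8.43	8.74	48	5.9	FALSE
Q4	2R	pB	8.1	68.8	68.5	69.2	9.65	9.54	9.81	26	4.5	FALSE
Q5	2R	pB	9.8	75.2	73.6	76.3	11.49	11.11	11.76	68	5.4	FALSE
Q6	2R	pB	9.1	83.9	82.9	84.1	13.77	13.46	13.83	69	5.1	FALSE
Q7	2R	pB	9.1	88.1	87.5	89.0	15.23	15.02	15.58	74	5.0	FALSE
Q8	3L	pB	10.4	46.4	46.0	47.1	20.56	19.89	24.36	398	5.8	TRUE
Q9	3R	pA	10.2	54.4	54.1	55.2	9.87	9.73	10.41	79	5.7	FALSE
Q10	3R	pB	9.1	62.5	62.4	63.4	14.01	13.98	14.36	61	5.1	FALSE
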