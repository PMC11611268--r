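dataset	disease	total_samples	control_samples	patient_samples	n_taxa	n_annotations
Cirrhosis	Liver Cirrhosis	232	114	118	542	10434
Colorectal	Colorectal Cancer	121	73	48	503	10635
Obesity	Obesity	253	89	164	465	11341
WT2D	Type 2 Diabetes (European women)	96	43	53	381	10180
T2D	Type 2 Diabetes (Chinese cohort)	344	174	170	572	10275
IBD	Inflammatory Bowel Disease	110	85	25	443	10196
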