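# Reconstruction summaries for the SOS (6 genes, 7 gold edges) and E. coli
# (8 genes, 15 gold edges) benchmark networks: true-positive and
# false-positive edge counts of each method over the m^2 ordered gene pairs
# (self-loops included).  TN and FN follow from m and n_gold.
network	method	m	n_gold	tp	fp
sos	cvode	6	7	7	17
sos	ode	6	7	5	18
ecoli	cvode	8	15	14	20
ecoli	ode	8	15	12	19
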