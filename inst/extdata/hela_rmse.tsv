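# Per-gene test-window prediction RMSE reported for the five-gene human
# cell-cycle benchmark under the real-valued (ode) and complex-valued
# (cvode) model variants.
gene	ode	cvode
Gene1	0.227851	0.125126
Gene2	0.11358	0.066308
Gene3	0.363917	0.123348
Gene4	0.340177	0.2797
Gene5	0.328782	0.10551
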