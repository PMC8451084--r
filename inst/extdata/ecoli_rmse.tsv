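# Per-gene test-window prediction RMSE reported for the eight-gene E. coli
# benchmark under the real-valued (ode) and complex-valued (cvode) model
# variants.
gene	ode	cvode
Crp	0.013349	0.010013
araC	0.058062	0.031771
nagC	0.01153	0.020923
chbC	0.041527	0.018565
araE	0.008005	0.024344
araA	0.023222	0.033139
chbA	0.028299	0.015565
chbF	0.031919	0.016927
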