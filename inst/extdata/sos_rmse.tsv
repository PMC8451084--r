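# Per-gene test-window prediction RMSE reported for the six-gene SOS DNA
# repair benchmark under the real-valued (ode) and complex-valued (cvode)
# model variants.
gene	ode	cvode
uvrD	0.014345	0.007601
lexA	0.075643	0.072955
umuD	0.017476	0.008536
recA	0.164121	0.076576
uvrA	0.168299	0.122481
polB	0.004601	0.003229
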