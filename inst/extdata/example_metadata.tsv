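sample	condition	timepoint_h	replicate
flfl_t0_r1	flfl	0	1
flfl_t0_r2	flfl	0	2
flfl_t0_r3	flfl	0	3
flfl_t0_r4	flfl	0	4
flfl_t20_r1	flfl	20	1
flfl_t20_r2	flfl	20	2
flfl_t20_r3	flfl	20	3
flfl_t20_r4	flfl	20	4
r26_t0_r1	r26	0	1
r26_t0_r2	r26	0	2
r26_t0_r3	r26	0	3
r26_t0_r4	r26	0	4
r26_t20_r1	r26	20	1
r26_t20_r2	r26	20	2
r26_t20_r3	r26	20	3
r26_t20_r4	r26	20	4
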