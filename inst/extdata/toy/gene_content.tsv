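taxon	a1	a2	b1	c1	c2	d1	e1	e2
T1	1	0	1	0	0	0	0	0
T2	0	1	0	0	0	0	0	0
T3	0	0	1	0	0	0	0	0
T4	0	0	0	1	1	0	0	0
T5	0	0	0	0	0	1	0	0
T6	0	0	0	0	0	0	1	1
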