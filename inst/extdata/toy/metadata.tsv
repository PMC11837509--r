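sample_id	individual	week	treatment
s_ctl_I1_w1	ctl_I1	1	control
s_ctl_I1_w2	ctl_I1	2	control
s_ctl_I2_w1	ctl_I2	1	control
s_ctl_I2_w2	ctl_I2	2	control
s_prt_I3_w1	prt_I3	1	perturbed
s_prt_I3_w2	prt_I3	2	perturbed
s_prt_I4_w1	prt_I4	1	perturbed
s_prt_I4_w2	prt_I4	2	perturbed
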