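taxon	s_ctl_I1_w1	s_ctl_I1_w2	s_ctl_I2_w1	s_ctl_I2_w2	s_prt_I3_w1	s_prt_I3_w2	s_prt_I4_w1	s_prt_I4_w2
T1	1000	1010	990	1005	1500	1490	1510	1500
T2	1100	1090	1110	1095	1480	1500	1490	1505
T3	900	905	895	910	1520	1510	1500	1495
T4	1050	1045	1055	1040	1500	0	1495	0
T5	950	955	945	960	0	1500	0	1510
T6	1000	995	1005	990	0	0	0	0
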