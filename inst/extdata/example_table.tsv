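feature_id	east_control_u1_h	east_control_u1_s	east_control_u2_h	east_control_u2_s	east_control_u3_h	east_control_u3_s
asv0001	9	5	52	19	49	37
asv0002	5	7	0	1	1	0
asv0003	14	0	12	1	29	0
asv0004	7	16	6	21	23	30
asv0005	2	0	2	8	0	0
asv0006	1	9	9	23	17	13
asv0007	4	37	42	12	26	17
asv0008	20	20	21	15	4	21
asv0009	0	3	56	3	70	8
asv0010	8	0	4	0	6	5
asv0011	31	61	115	81	69	85
asv0012	64	1	3	7	95	2
asv0013	6	16	0	15	1	11
asv0014	1	23	14	69	11	35
asv0015	3	24	17	17	12	24
asv0016	9	83	15	62	95	128
asv0017	18	51	5	73	39	75
asv0018	0	0	0	0	0	0
asv0019	0	18	10	15	13	8
asv0020	43	24	2	7	17	2
asv0021	5	14	9	2	3	12
asv0022	2	20	0	38	4	14
asv0023	25	5	13	0	3	2
asv0024	20	26	23	3	17	7
asv0025	16	48	65	36	17	24
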