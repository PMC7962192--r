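protein_id	position	label
synth0001	24	0
synth0001	49	1
synth0002	49	1
synth0002	56	0
synth0002	61	0
synth0002	64	0
synth0002	82	1
synth0003	30	0
synth0003	37	0
synth0003	59	1
synth0003	67	0
synth0003	68	0
synth0004	5	0
synth0004	34	0
synth0004	58	1
synth0004	62	0
synth0005	24	0
synth0005	31	1
synth0005	35	1
synth0005	53	0
synth0005	77	0
synth0005	98	0
synth0005	114	1
synth0005	126	0
synth0006	9	1
synth0006	36	0
synth0006	61	0
synth0006	90	0
synth0006	92	0
synth0007	21	1
synth0007	37	0
synth0007	54	0
synth0007	59	0
synth0008	5	1
synth0008	16	0
synth0008	22	0
synth0008	28	0
synth0008	40	0
synth0008	42	0
synth0008	68	1
synth0008	98	0
synth0008	122	0
synth0009	3	0
synth0009	39	0
synth0010	18	0
synth0010	42	0
synth0010	83	1
synth0010	101	0
synth0010	103	0
synth0011	2	1
synth0011	10	1
synth0011	26	0
synth0011	32	1
synth0011	40	0
synth0011	50	1
synth0011	52	0
synth0012	27	0
synth0012	35	0
synth0012	61	0
synth0012	91	0
synth0012	98	0
synth0012	100	0
synth0012	124	0
synth0012	129	1
synth0013	64	0
synth0013	79	1
synth0013	89	0
synth0014	2	1
synth0014	18	0
synth0014	38	0
synth0014	46	0
synth0014	78	0
synth0015	3	1
synth0015	16	0
synth0015	93	0
synth0016	20	0
synth0016	45	1
synth0016	54	0
synth0016	55	0
synth0016	78	1
synth0016	101	1
synth0017	38	1
synth0017	58	1
synth0017	100	0
synth0017	127	0
synth0018	5	0
synth0018	12	0
synth0018	30	1
synth0018	34	0
synth0018	37	0
synth0018	69	1
synth0019	16	0
synth0019	31	1
synth0019	53	1
synth0019	70	0
synth0019	77	0
synth0019	92	0
synth0019	102	0
synth0019	118	0
synth0019	125	0
synth0020	1	1
synth0020	41	1
synth0020	65	0
synth0020	71	1
synth0020	80	0
synth0021	56	1
synth0021	99	1
synth0021	120	1
synth0022	6	1
synth0022	7	1
synth0022	24	1
synth0022	30	0
synth0022	38	0
synth0022	50	1
synth0022	55	1
synth0022	87	1
synth0023	8	0
synth0023	15	0
synth0023	83	1
synth0024	8	1
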