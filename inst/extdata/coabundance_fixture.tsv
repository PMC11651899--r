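sample_id	A1	A2	A3	A4	B1	B2	C1	C2	C3	C4
s1	10	12	70	25	11	80	5	6	7	50
s2	50	55	10	95	22	70	40	44	48	10
s3	20	24	90	15	33	60	10	12	14	70
s4	80	88	30	45	44	50	60	66	72	20
s5	30	33	100	85	55	40	15	17	19	90
s6	90	99	20	35	66	30	70	77	84	5
s7	40	44	60	75	77	20	20	22	24	30
s8	100	110	40	5	88	10	80	88	96	60
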