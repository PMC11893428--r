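name	residue_index	imgt_position
IGHV3-3*01	1	1
IGHV3-3*01	2	2
IGHV3-3*01	3	3
IGHV3-3*01	4	4
IGHV3-3*01	5	5
IGHV3-3*01	6	6
IGHV3-3*01	7	7
IGHV3-3*01	8	8
IGHV3-3*01	9	9
IGHV3-3*01	10	11
IGHV3-3*01	11	12
IGHV3-3*01	12	13
IGHV3-3*01	13	14
IGHV3-3*01	14	15
IGHV3-3*01	15	16
IGHV3-3*01	16	17
IGHV3-3*01	17	18
IGHV3-3*01	18	19
IGHV3-3*01	19	20
IGHV3-3*01	20	21
IGHV3-3*01	21	22
IGHV3-3*01	22	23
IGHV3-3*01	23	24
IGHV3-3*01	24	25
IGHV3-3*01	25	26
IGHV3-3*01	26	27
IGHV3-3*01	27	28
IGHV3-3*01	28	29
IGHV3-3*01	29	30
IGHV3-3*01	30	35
IGHV3-3*01	31	36
IGHV3-3*01	32	37
IGHV3-3*01	33	38
IGHV3-3*01	34	39
IGHV3-3*01	35	40
IGHV3-3*01	36	41
IGHV3-3*01	37	42
IGHV3-3*01	38	43
IGHV3-3*01	39	44
IGHV3-3*01	40	45
IGHV3-3*01	41	46
IGHV3-3*01	42	47
IGHV3-3*01	43	48
IGHV3-3*01	44	49
IGHV3-3*01	45	50
IGHV3-3*01	46	51
IGHV3-3*01	47	52
IGHV3-3*01	48	53
IGHV3-3*01	49	54
IGHV3-3*01	50	55
IGHV3-3*01	51	56
IGHV3-3*01	52	57
IGHV3-3*01	53	58
IGHV3-3*01	54	59
IGHV3-3*01	55	62
IGHV3-3*01	56	63
IGHV3-3*01	57	64
IGHV3-3*01	58	65
IGHV3-3*01	59	66
IGHV3-3*01	60	67
IGHV3-3*01	61	68
IGHV3-3*01	62	69
IGHV3-3*01	63	70
IGHV3-3*01	64	71
IGHV3-3*01	65	72
IGHV3-3*01	66	74
IGHV3-3*01	67	75
IGHV3-3*01	68	76
IGHV3-3*01	69	77
IGHV3-3*01	70	78
IGHV3-3*01	71	79
IGHV3-3*01	72	80
IGHV3-3*01	73	81
IGHV3-3*01	74	82
IGHV3-3*01	75	83
IGHV3-3*01	76	84
IGHV3-3*01	77	85
IGHV3-3*01	78	86
IGHV3-3*01	79	87
IGHV3-3*01	80	88
IGHV3-3*01	81	89
IGHV3-3*01	82	90
IGHV3-3*01	83	91
IGHV3-3*01	84	92
IGHV3-3*01	85	93
IGHV3-3*01	86	94
IGHV3-3*01	87	95
IGHV3-3*01	88	96
IGHV3-3*01	89	97
IGHV3-3*01	90	98
IGHV3-3*01	91	99
IGHV3-3*01	92	100
IGHV3-3*01	93	101
IGHV3-3*01	94	102
IGHV3-3*01	95	103
IGHV3-3*01	96	104
IGHV3S53*01	1	1
IGHV3S53*01	2	2
IGHV3S53*01	3	3
IGHV3S53*01	4	4
IGHV3S53*01	5	5
IGHV3S53*01	6	6
IGHV3S53*01	7	7
IGHV3S53*01	8	8
IGHV3S53*01	9	9
IGHV3S53*01	10	11
IGHV3S53*01	11	12
IGHV3S53*01	12	13
IGHV3S53*01	13	14
IGHV3S53*01	14	15
IGHV3S53*01	15	16
IGHV3S53*01	16	17
IGHV3S53*01	17	18
IGHV3S53*01	18	19
IGHV3S53*01	19	20
IGHV3S53*01	20	21
IGHV3S53*01	21	22
IGHV3S53*01	22	23
IGHV3S53*01	23	24
IGHV3S53*01	24	25
IGHV3S53*01	25	26
IGHV3S53*01	26	27
IGHV3S53*01	27	28
IGHV3S53*01	28	29
IGHV3S53*01	29	30
IGHV3S53*01	30	35
IGHV3S53*01	31	36
IGHV3S53*01	32	37
IGHV3S53*01	33	38
IGHV3S53*01	34	39
IGHV3S53*01	35	40
IGHV3S53*01	36	41
IGHV3S53*01	37	42
IGHV3S53*01	38	43
IGHV3S53*01	39	44
IGHV3S53*01	40	45
IGHV3S53*01	41	46
IGHV3S53*01	42	47
IGHV3S53*01	43	48
IGHV3S53*01	44	49
IGHV3S53*01	45	50
IGHV3S53*01	46	51
IGHV3S53*01	47	52
IGHV3S53*01	48	53
IGHV3S53*01	49	54
IGHV3S53*01	50	55
IGHV3S53*01	51	56
IGHV3S53*01	52	57
IGHV3S53*01	53	58
IGHV3S53*01	54	59
IGHV3S53*01	55	63
IGHV3S53*01	56	64
IGHV3S53*01	57	65
IGHV3S53*01	58	66
IGHV3S53*01	59	67
IGHV3S53*01	60	68
IGHV3S53*01	61	69
IGHV3S53*01	62	70
IGHV3S53*01	63	71
IGHV3S53*01	64	72
IGHV3S53*01	65	74
IGHV3S53*01	66	75
IGHV3S53*01	67	76
IGHV3S53*01	68	77
IGHV3S53*01	69	78
IGHV3S53*01	70	79
IGHV3S53*01	71	80
IGHV3S53*01	72	81
IGHV3S53*01	73	82
IGHV3S53*01	74	83
IGHV3S53*01	75	84
IGHV3S53*01	76	85
IGHV3S53*01	77	86
IGHV3S53*01	78	87
IGHV3S53*01	79	88
IGHV3S53*01	80	89
IGHV3S53*01	81	90
IGHV3S53*01	82	91
IGHV3S53*01	83	92
IGHV3S53*01	84	93
IGHV3S53*01	85	94
IGHV3S53*01	86	95
IGHV3S53*01	87	96
IGHV3S53*01	88	97
IGHV3S53*01	89	98
IGHV3S53*01	90	99
IGHV3S53*01	91	100
IGHV3S53*01	92	101
IGHV3S53*01	93	102
IGHV3S53*01	94	103
IGHV3S53*01	95	104
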