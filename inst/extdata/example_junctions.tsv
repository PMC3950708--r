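junction	mate_pairs	assembled	left_length	right_length	repeat_left	repeat_right	genes_covered
J0001	24	TRUE	112	98	FALSE	FALSE	1
J0002	9	TRUE	140	121	FALSE	FALSE	1
J0003	31	FALSE	88	92	FALSE	FALSE	1
J0004	18	TRUE	70	70	FALSE	FALSE	2
J0005	45	TRUE	65	130	FALSE	FALSE	1
J0006	27	TRUE	105	88	TRUE	FALSE	1
J0007	52	TRUE	96	143	FALSE	FALSE	3
J0008	10	TRUE	77	84	FALSE	FALSE	1
J0009	12	TRUE	101	69	FALSE	FALSE	2
J0010	33	TRUE	120	111	FALSE	TRUE	1
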