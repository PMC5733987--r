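protein	lysine	nearest_acid	acid_dist	acid_censored	nearest_base	base_dist	base_censored	netglycate	distance_call
3K4Q	68	Glu_205	8.26	FALSE	Lys_70	6.51	FALSE	TRUE	TRUE
3K4Q	70	Asp_66	4.09	FALSE	Lys_68	6.51	FALSE	FALSE	TRUE
3K4Q	71	Glu_233	9.89	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	89	Asp_223	5.68	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	94		13.98	TRUE		13.06	TRUE	FALSE	FALSE
3K4Q	119	Asp_405	4.21	FALSE		NA	FALSE	FALSE	TRUE
3K4Q	148		NA	FALSE	Lys_149	9.73	FALSE	FALSE	TRUE
3K4Q	149	Glu_152	4.52	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	158	Asp_161	7.65	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	160	Asp_161	9.97	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	172	Asp_174	4.5	FALSE		NA	FALSE	TRUE	TRUE
3K4Q	254	Asp_244	9.84	FALSE		NA	FALSE	FALSE	TRUE
3K4Q	277	Glu_205	4.28	FALSE	Lys_278	6.72	FALSE	FALSE	TRUE
3K4Q	278		NA	FALSE	His_282	6.51	FALSE	FALSE	TRUE
3K4Q	356	Asp_370	8.5	FALSE		NA	FALSE	FALSE	TRUE
1QFX_A	14	Glu_19	8.26	FALSE		NA	FALSE	TRUE	TRUE
1QFX_A	28	Asp_22	6.95	FALSE	His_29	8.6	FALSE	FALSE	TRUE
1QFX_A	61	Asp_125	6.56	FALSE	His_129	4.4	FALSE	FALSE	TRUE
1QFX_A	74	Glu_78	4.51	FALSE		NA	FALSE	FALSE	TRUE
1QFX_A	82	Asp_236	4.15	FALSE		NA	FALSE	FALSE	TRUE
1QFX_A	92	Glu_90	4.61	FALSE		NA	FALSE	FALSE	TRUE
1QFX_A	134		NA	FALSE	His_139	9.21	FALSE	FALSE	TRUE
1QFX_A	163	Glu_166	4.74	FALSE	Arg_447	9.84	FALSE	FALSE	TRUE
1QFX_A	217		11.97	TRUE		13.15	TRUE	FALSE	FALSE
1QFX_A	285	Glu_284	7.35	FALSE		NA	FALSE	FALSE	TRUE
1QFX_A	307	Glu_308	9.81	FALSE		NA	FALSE	TRUE	TRUE
1QFX_A	413		29.31	TRUE		23.84	TRUE	TRUE	FALSE
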