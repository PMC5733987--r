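0918cedd8ee0eb0d26bfa28314f77983b99f741605fe49bcb6e5eb1758930e23	accessibility_janin.tsv
7365d99dc8b16532a0be7476a0a72c72fe6fdfe665989f4f668c8b71cd8aa6d9	diwv.tsv
0b39773a406dcc75f7c9b419337c7d33c65a318d9aaa7c3a03f174e4b00e8983	kd.tsv
0db82b982edeca8add737647243198b01ddeece73f2e11c866a2cddf2076bf6d	kt_propensity.tsv
b61e4daeb14ba38e2512c80dbf9760b6f79b868c62f2dc91f4d3f2912a47f8a0	nend_rule.tsv
d3b7b5ddb98663bb09fa2b69e643e240dae780a5bb64c5f85cd829ef1c0c0408	pka.tsv
e4c86c01984717d5926262a146bd490e03a3eaa21b4a507170cc1b991a3c0f2b	residue_mass.tsv
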