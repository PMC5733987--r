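protein	pdb_id	chain	precursor_length	signal_peptide	mature_length	nterm
3K4Q	3K4Q	A	467	23	444	A
1QFX_A	1QFX	A	479	19	460	F
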