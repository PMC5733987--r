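protein	fragment	start	end	sequence	length
3K4Q	1	23	58	HLWGQYAPFFSLANESVISPEVPAGCRVTFAQVLSR	36
3K4Q	2	374	420	SAWTVPFASRLYVEMMQCQAEQEPLVRVLVNDRVVPLHGCPVDALGR	47
1QFX_A	1	322	336	ITPILAALGVLIPNE	15
1QFX_A	2	378	392	TYVRLVLNEAVLPFN	15
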