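a241c1c81c0026b2f4d46c34efca0000ef647139d1c93afd25eb76dd3e894096	composition_1QFX_A.tsv
190fb98afa26a615fddad512f589bf9a3d16be1ef746894bef69d9eb3efd0a26	composition_3K4Q.tsv
10886131203f9ebe1f4779c1c23e4054495bb87533ef0ccb15f8776507b2768a	proteins.tsv
13e7f876f907ca19f9b8e219c29ba427509f638040dc01dca3061a7ce207a637	table4_glycation.tsv
ff16ad0957846366eabef5307616a0b07af645be318f0e04a290a9c713f4d765	table5_determinants.tsv
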