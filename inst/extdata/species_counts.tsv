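species	n_genomes	n_positive	n_copies	n_full
Bacillus cereus	152	126	687	520
Clostridioides difficile	133	132	1875	1760
Deinococcus radiodurans	12	12	44	44
Escherichia coli	2467	2325	4825	4412
Helicobacter pylori	335	214	734	678
Salmonella enterica	1495	658	1831	757
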