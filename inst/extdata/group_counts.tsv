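species	n_genomes	label	n_positive
Bacillus cereus	152	IS605a	0
Bacillus cereus	152	IS605b	82
Bacillus cereus	152	IS605c	0
Bacillus cereus	152	IS605_total	82
Bacillus cereus	152	IS607a	39
Bacillus cereus	152	IS607b	12
Bacillus cereus	152	IS607_total	48
Bacillus cereus	152	IS1341	112
Clostridioides difficile	133	IS605a	56
Clostridioides difficile	133	IS605b	132
Clostridioides difficile	133	IS605c	0
Clostridioides difficile	133	IS605_total	132
Clostridioides difficile	133	IS607a	0
Clostridioides difficile	133	IS607b	15
Clostridioides difficile	133	IS607_total	15
Clostridioides difficile	133	IS1341	106
Deinococcus radiodurans	12	IS605a	12
Deinococcus radiodurans	12	IS605b	0
Deinococcus radiodurans	12	IS605c	0
Deinococcus radiodurans	12	IS605_total	12
Deinococcus radiodurans	12	IS607a	0
Deinococcus radiodurans	12	IS607b	0
Deinococcus radiodurans	12	IS607_total	0
Deinococcus radiodurans	12	IS1341	0
Escherichia coli	2467	IS605a	0
Escherichia coli	2467	IS605b	0
Escherichia coli	2467	IS605c	2242
Escherichia coli	2467	IS605_total	2242
Escherichia coli	2467	IS607a	0
Escherichia coli	2467	IS607b	0
Escherichia coli	2467	IS607_total	0
Escherichia coli	2467	IS1341	312
Helicobacter pylori	335	IS605a	58
Helicobacter pylori	335	IS605b	0
Helicobacter pylori	335	IS605c	123
Helicobacter pylori	335	IS605_total	177
Helicobacter pylori	335	IS607a	81
Helicobacter pylori	335	IS607b	0
Helicobacter pylori	335	IS607_total	81
Helicobacter pylori	335	IS1341	0
Salmonella enterica	1495	IS605a	0
Salmonella enterica	1495	IS605b	0
Salmonella enterica	1495	IS605c	303
Salmonella enterica	1495	IS605_total	303
Salmonella enterica	1495	IS607a	0
Salmonella enterica	1495	IS607b	0
Salmonella enterica	1495	IS607_total	0
Salmonella enterica	1495	IS1341	418
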