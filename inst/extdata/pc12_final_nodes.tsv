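node	role	late_gene
NGF	stimulus	0
RAS	hidden	0
PI3K	inhibited	0
PLC	hidden	0
MEK_ERK	inhibited	0
AKT	hidden	0
JNK	inhibited	0
Jund	measured	0
Junb	measured	0
Fosl1	measured	0
Fos	measured	0
Egr1	measured	0
AP1	hidden	0
Zfp36	measured	0
Klf4	measured	0
Btg2	measured	0
uPA	hidden	0
uPAR	hidden	0
Plasmin	hidden	0
Mmp10	measured	1
Mmp3	measured	1
Itga1	measured	0
FAK	hidden	0
Serpine1	measured	1
Npy	measured	1
NPYY1	hidden	0
Maff	measured	0
Klf10	measured	0
Klf2	measured	1
Klf5	measured	1
Cited2	measured	1
CellDiff	readout	0
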