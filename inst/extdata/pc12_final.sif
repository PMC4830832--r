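# PC12 NGF differentiation: final Boolean model (32 nodes, 52 edges).
# Synthetic reconstruction from published main-text statements (fixed-edge
# list, pathway and feedback descriptions); the original supplementary
# transition tables were not available for transcription.
# Columns: source<TAB>sign<TAB>target<TAB>fixed
NGF	1	RAS	1
Mmp10	1	RAS	1
NGF	1	PI3K	1
NGF	1	PLC	1
NPYY1	1	PLC	0
RAS	1	MEK_ERK	1
PLC	1	MEK_ERK	1
FAK	1	MEK_ERK	0
PI3K	1	AKT	0
NGF	1	JNK	0
FAK	1	JNK	0
MEK_ERK	1	Jund	1
JNK	1	Jund	1
MEK_ERK	1	Junb	1
JNK	1	Junb	1
JNK	1	Fosl1	0
MEK_ERK	1	Fos	0
MEK_ERK	1	Egr1	0
Fosl1	1	AP1	1
Jund	1	AP1	1
AP1	1	AP1	0
Zfp36	-1	AP1	0
MEK_ERK	1	Zfp36	0
JNK	1	Zfp36	0
Zfp36	-1	Zfp36	0
AP1	-1	Zfp36	0
Egr1	1	Klf4	0
Fosl1	1	Klf4	0
Klf4	-1	Klf4	0
AP1	-1	Klf4	0
Egr1	1	Btg2	0
Fosl1	1	Btg2	0
Btg2	-1	Btg2	0
AP1	-1	Btg2	0
AP1	1	uPA	0
uPA	1	uPAR	0
uPAR	1	Plasmin	0
Plasmin	1	Mmp10	0
Plasmin	1	Mmp3	0
Mmp10	1	Itga1	0
Mmp3	1	Itga1	0
Itga1	1	FAK	0
AP1	1	Serpine1	0
AP1	1	Npy	1
Npy	1	NPYY1	0
AKT	1	Maff	0
AKT	1	Klf10	0
FAK	1	Klf2	0
FAK	1	Klf5	0
FAK	1	Cited2	0
uPAR	1	CellDiff	0
Klf5	1	CellDiff	0
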