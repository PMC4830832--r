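# PC12 NGF differentiation: prior-knowledge network (63 nodes, 109 edges).
# Synthetic reconstruction from published main-text statements; see the
# package methods vignette for transcription precedence.
# Columns: source<TAB>sign<TAB>target<TAB>fixed
NGF	1	TrkA	0
TrkA	1	SHC	0
SHC	1	GRB2	0
GRB2	1	SOS	0
SOS	1	RAS	0
NGF	1	RAS	1
NGF	1	PI3K	1
NGF	1	PLC	1
RAS	1	RAF	0
RAF	1	MEK	0
RAS	1	MEK	1
PLC	1	MEK	1
MEK	1	ERK	0
PI3K	1	PDK1	0
PDK1	1	AKT	0
PI3K	1	AKT	0
PLC	1	PKC	0
PKC	1	RAF	0
PKC	1	MEK	0
TrkA	1	MKK4	0
MKK4	1	JNK	0
TrkA	1	MKK3	0
MKK3	1	P38	0
JNK	1	JUN	0
JUN	1	AP1	0
ERK	1	Fosl1	0
JNK	1	Fosl1	0
ERK	1	Fos	0
ERK	1	Egr1	0
ERK	1	Elk1	0
Elk1	1	Fos	0
Elk1	1	Egr1	0
ERK	1	Jund	1
JNK	1	Jund	1
ERK	1	Junb	1
JNK	1	Junb	1
Fosl1	1	AP1	1
Jund	1	AP1	1
Fos	1	AP1	0
Junb	1	AP1	0
ERK	1	Zfp36	0
JNK	1	Zfp36	0
Egr1	1	Klf4	0
Fosl1	1	Klf4	0
Egr1	1	Btg2	0
Fosl1	1	Btg2	0
AP1	1	uPA	0
AP1	1	Plat	0
AP1	1	Plaur	0
Plaur	1	uPAR	0
uPA	1	uPAR	0
Plat	1	Plasmin	0
uPAR	1	Plasmin	0
Plasmin	1	Mmp3	0
Plasmin	1	Mmp10	0
Plasmin	1	Mmp13	0
Mmp3	1	Itga1	0
Mmp10	1	Itga1	0
Mmp13	1	Itga1	0
Itga1	1	FAK	0
FAK	1	SHC	0
Mmp10	1	RAS	1
AP1	1	Serpine1	0
Serpine1	-1	Plasmin	0
AP1	1	Npy	1
Npy	1	NPYY1	0
NPYY1	1	PKC	0
NPYY1	1	PLC	0
AKT	1	Maff	0
AKT	1	Klf10	0
FAK	1	Klf2	0
FAK	1	Klf5	0
FAK	1	Klf6	0
FAK	1	Cited2	0
ERK	1	Dusp6	0
Dusp6	-1	ERK	0
ERK	1	Atf3	0
P38	1	Atf3	0
Atf3	-1	Egr1	0
Zfp36l2	-1	Egr1	0
Zfp36l2	-1	Fos	0
Zfp36l2	-1	Junb	0
ERK	1	Zfp36l2	0
AP1	1	Vgf	0
AP1	1	Tnfrsf12a	0
AP1	1	Dclk1	0
P38	1	Gadd45a	0
AP1	1	Gadd45a	0
AP1	1	Coro1a	0
ERK	1	Rasa2	0
Rasa2	-1	RAS	0
AP1	1	IL6	0
IL6	1	Stat3	0
Stat3	1	Klf6	0
ERK	1	CREB	0
CREB	1	Fos	0
ERK	1	SRF	0
SRF	1	Fos	0
SRF	1	Egr1	0
AKT	-1	RAF	0
Klf5	1	CellDiff	0
Npy	1	CellDiff	0
uPAR	1	CellDiff	0
Vgf	1	CellDiff	0
ERK	1	Dusp1	0
Dusp1	-1	JNK	0
Klf4	-1	Klf4	0
Btg2	-1	Btg2	0
TrkA	1	PI3K	0
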