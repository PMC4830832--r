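node	role
NGF	stimulus
MEK	inhibited
JNK	inhibited
PI3K	inhibited
CellDiff	readout
Fosl1	measured
Fos	measured
Junb	measured
Jund	measured
Egr1	measured
Zfp36	measured
Klf4	measured
Btg2	measured
Plat	measured
Plaur	measured
Mmp3	measured
Mmp10	measured
Mmp13	measured
Itga1	measured
Serpine1	measured
Npy	measured
Maff	measured
Klf10	measured
Klf2	measured
Klf5	measured
Klf6	measured
Cited2	measured
Dusp6	measured
Atf3	measured
Vgf	measured
Tnfrsf12a	measured
Dclk1	measured
Gadd45a	measured
Coro1a	measured
Rasa2	measured
IL6	measured
Zfp36l2	measured
Dusp1	measured
TrkA	hidden
SHC	hidden
GRB2	hidden
SOS	hidden
RAS	hidden
RAF	hidden
ERK	hidden
PDK1	hidden
AKT	hidden
PLC	hidden
PKC	hidden
MKK4	hidden
MKK3	hidden
P38	hidden
JUN	hidden
AP1	hidden
uPA	hidden
uPAR	hidden
Plasmin	hidden
FAK	hidden
NPYY1	hidden
Stat3	hidden
CREB	hidden
SRF	hidden
Elk1	hidden
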