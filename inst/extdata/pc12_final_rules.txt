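# Transition rules of the final PC12 Boolean model.
# NGF is an input node (self-maintaining unless clamped).
RAS = NGF | Mmp10
PI3K = NGF
PLC = NGF | NPYY1
MEK_ERK = RAS | PLC | FAK
AKT = PI3K
JNK = NGF | FAK
Jund = MEK_ERK & JNK
Junb = MEK_ERK & JNK
Fosl1 = JNK
Fos = MEK_ERK
Egr1 = MEK_ERK
AP1 = Fosl1 & Jund & (AP1 | !Zfp36)
Zfp36 = MEK_ERK & JNK & !Zfp36 & !AP1
Klf4 = Egr1 & Fosl1 & !Klf4 & !AP1
Btg2 = Egr1 & Fosl1 & !Btg2 & !AP1
uPA = AP1
uPAR = uPA
Plasmin = uPAR
Mmp10 = Plasmin
Mmp3 = Plasmin
Itga1 = Mmp10 | Mmp3
FAK = Itga1
Serpine1 = AP1
Npy = AP1
NPYY1 = Npy
Maff = AKT
Klf10 = AKT
Klf2 = FAK
Klf5 = FAK
Cited2 = FAK
CellDiff = uPAR & Klf5
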