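# Generates the PC12 fixture files under inst/extdata and sanity-checks
# counts and dynamics. Run from /root/pkg.

final_edges <- read.table(text = "
NGF 1 RAS 1
Mmp10 1 RAS 1
NGF 1 PI3K 1
NGF 1 PLC 1
NPYY1 1 PLC 0
RAS 1 MEK_ERK 1
PLC 1 MEK_ERK 1
FAK 1 MEK_ERK 0
PI3K 1 AKT 0
NGF 1 JNK 0
FAK 1 JNK 0
MEK_ERK 1 Jund 1
JNK 1 Jund 1
MEK_ERK 1 Junb 1
JNK 1 Junb 1
JNK 1 Fosl1 0
MEK_ERK 1 Fos 0
MEK_ERK 1 Egr1 0
Fosl1 1 AP1 1
Jund 1 AP1 1
AP1 1 AP1 0
Zfp36 -1 AP1 0
MEK_ERK 1 Zfp36 0
JNK 1 Zfp36 0
Zfp36 -1 Zfp36 0
AP1 -1 Zfp36 0
Egr1 1 Klf4 0
Fosl1 1 Klf4 0
Klf4 -1 Klf4 0
AP1 -1 Klf4 0
Egr1 1 Btg2 0
Fosl1 1 Btg2 0
Btg2 -1 Btg2 0
AP1 -1 Btg2 0
AP1 1 uPA 0
uPA 1 uPAR 0
uPAR 1 Plasmin 0
Plasmin 1 Mmp10 0
Plasmin 1 Mmp3 0
Mmp10 1 Itga1 0
Mmp3 1 Itga1 0
Itga1 1 FAK 0
AP1 1 Serpine1 0
AP1 1 Npy 1
Npy 1 NPYY1 0
AKT 1 Maff 0
AKT 1 Klf10 0
FAK 1 Klf2 0
FAK 1 Klf5 0
FAK 1 Cited2 0
uPAR 1 CellDiff 0
Klf5 1 CellDiff 0
", col.names = c("source", "sign", "target", "fixed"))

final_rules <- c(
  "RAS = NGF | Mmp10",
  "PI3K = NGF",
  "PLC = NGF | NPYY1",
  "MEK_ERK = RAS | PLC | FAK",
  "AKT = PI3K",
  "JNK = NGF | FAK",
  "Jund = MEK_ERK & JNK",
  "Junb = MEK_ERK & JNK",
  "Fosl1 = JNK",
  "Fos = MEK_ERK",
  "Egr1 = MEK_ERK",
  "AP1 = Fosl1 & Jund & (AP1 | !Zfp36)",
  "Zfp36 = MEK_ERK & JNK & !Zfp36 & !AP1",
  "Klf4 = Egr1 & Fosl1 & !Klf4 & !AP1",
  "Btg2 = Egr1 & Fosl1 & !Btg2 & !AP1",
  "uPA = AP1",
  "uPAR = uPA",
  "Plasmin = uPAR",
  "Mmp10 = Plasmin",
  "Mmp3 = Plasmin",
  "Itga1 = Mmp10 | Mmp3",
  "FAK = Itga1",
  "Serpine1 = AP1",
  "Npy = AP1",
  "NPYY1 = Npy",
  "Maff = AKT",
  "Klf10 = AKT",
  "Klf2 = FAK",
  "Klf5 = FAK",
  "Cited2 = FAK",
  "CellDiff = uPAR & Klf5")

final_nodes <- data.frame(
  node = c("NGF", "RAS", "PI3K", "PLC", "MEK_ERK", "AKT", "JNK", "Jund",
           "Junb", "Fosl1", "Fos", "Egr1", "AP1", "Zfp36", "Klf4", "Btg2",
           "uPA", "uPAR", "Plasmin", "Mmp10", "Mmp3", "Itga1", "FAK",
           "Serpine1", "Npy", "NPYY1", "Maff", "Klf10", "Klf2", "Klf5",
           "Cited2", "CellDiff"),
  role = c("stimulus", "hidden", "inhibited", "hidden", "inhibited", "hidden",
           "inhibited", "measured", "measured", "measured", "measured",
           "measured", "hidden", "measured", "measured", "measured",
           "hidden", "hidden", "hidden", "measured", "measured", "measured",
           "hidden", "measured", "measured", "hidden", "measured", "measured",
           "measured", "measured", "measured", "readout"))
final_nodes$late_gene <- as.integer(final_nodes$node %in%
  c("Klf2", "Klf5", "Cited2", "Npy", "Serpine1", "Mmp3", "Mmp10"))

pkn_edges <- read.table(text = "
NGF 1 TrkA 0
TrkA 1 SHC 0
SHC 1 GRB2 0
GRB2 1 SOS 0
SOS 1 RAS 0
NGF 1 RAS 1
NGF 1 PI3K 1
NGF 1 PLC 1
RAS 1 RAF 0
RAF 1 MEK 0
RAS 1 MEK 1
PLC 1 MEK 1
MEK 1 ERK 0
PI3K 1 PDK1 0
PDK1 1 AKT 0
PI3K 1 AKT 0
PLC 1 PKC 0
PKC 1 RAF 0
PKC 1 MEK 0
TrkA 1 MKK4 0
MKK4 1 JNK 0
TrkA 1 MKK3 0
MKK3 1 P38 0
JNK 1 JUN 0
JUN 1 AP1 0
ERK 1 Fosl1 0
JNK 1 Fosl1 0
ERK 1 Fos 0
ERK 1 Egr1 0
ERK 1 Elk1 0
Elk1 1 Fos 0
Elk1 1 Egr1 0
ERK 1 Jund 1
JNK 1 Jund 1
ERK 1 Junb 1
JNK 1 Junb 1
Fosl1 1 AP1 1
Jund 1 AP1 1
Fos 1 AP1 0
Junb 1 AP1 0
ERK 1 Zfp36 0
JNK 1 Zfp36 0
Egr1 1 Klf4 0
Fosl1 1 Klf4 0
Egr1 1 Btg2 0
Fosl1 1 Btg2 0
AP1 1 uPA 0
AP1 1 Plat 0
AP1 1 Plaur 0
Plaur 1 uPAR 0
uPA 1 uPAR 0
Plat 1 Plasmin 0
uPAR 1 Plasmin 0
Plasmin 1 Mmp3 0
Plasmin 1 Mmp10 0
Plasmin 1 Mmp13 0
Mmp3 1 Itga1 0
Mmp10 1 Itga1 0
Mmp13 1 Itga1 0
Itga1 1 FAK 0
FAK 1 SHC 0
Mmp10 1 RAS 1
AP1 1 Serpine1 0
Serpine1 -1 Plasmin 0
AP1 1 Npy 1
Npy 1 NPYY1 0
NPYY1 1 PKC 0
NPYY1 1 PLC 0
AKT 1 Maff 0
AKT 1 Klf10 0
FAK 1 Klf2 0
FAK 1 Klf5 0
FAK 1 Klf6 0
FAK 1 Cited2 0
ERK 1 Dusp6 0
Dusp6 -1 ERK 0
ERK 1 Atf3 0
P38 1 Atf3 0
Atf3 -1 Egr1 0
Zfp36l2 -1 Egr1 0
Zfp36l2 -1 Fos 0
Zfp36l2 -1 Junb 0
ERK 1 Zfp36l2 0
AP1 1 Vgf 0
AP1 1 Tnfrsf12a 0
AP1 1 Dclk1 0
P38 1 Gadd45a 0
AP1 1 Gadd45a 0
AP1 1 Coro1a 0
ERK 1 Rasa2 0
Rasa2 -1 RAS 0
AP1 1 IL6 0
IL6 1 Stat3 0
Stat3 1 Klf6 0
ERK 1 CREB 0
CREB 1 Fos 0
ERK 1 SRF 0
SRF 1 Fos 0
SRF 1 Egr1 0
AKT -1 RAF 0
Klf5 1 CellDiff 0
Npy 1 CellDiff 0
uPAR 1 CellDiff 0
Vgf 1 CellDiff 0
ERK 1 Dusp1 0
Dusp1 -1 JNK 0
Klf4 -1 Klf4 0
Btg2 -1 Btg2 0
TrkA 1 PI3K 0
", col.names = c("source", "sign", "target", "fixed"))

pkn_measured <- c("Fosl1", "Fos", "Junb", "Jund", "Egr1", "Zfp36", "Klf4",
                  "Btg2", "Plat", "Plaur", "Mmp3", "Mmp10", "Mmp13", "Itga1",
                  "Serpine1", "Npy", "Maff", "Klf10", "Klf2", "Klf5", "Klf6",
                  "Cited2", "Dusp6", "Atf3", "Vgf", "Tnfrsf12a", "Dclk1",
                  "Gadd45a", "Coro1a", "Rasa2", "IL6", "Zfp36l2", "Dusp1")
pkn_hidden <- c("TrkA", "SHC", "GRB2", "SOS", "RAS", "RAF", "ERK", "PDK1",
                "AKT", "PLC", "PKC", "MKK4", "MKK3", "P38", "JUN", "AP1",
                "uPA", "uPAR", "Plasmin", "FAK", "NPYY1", "Stat3", "CREB",
                "SRF", "Elk1")
pkn_nodes <- data.frame(
  node = c("NGF", "MEK", "JNK", "PI3K", "CellDiff", pkn_measured, pkn_hidden),
  role = c("stimulus", "inhibited", "inhibited", "inhibited", "readout",
           rep("measured", length(pkn_measured)),
           rep("hidden", length(pkn_hidden))))

cat("final: edges", nrow(final_edges),
    "nodes", length(union(final_edges$source, final_edges$target)), "\n")
cat("pkn:   edges", nrow(pkn_edges),
    "nodes", length(union(pkn_edges$source, pkn_edges$target)), "\n")
stopifnot(nrow(final_edges) == 52,
          length(union(final_edges$source, final_edges$target)) == 32,
          nrow(pkn_edges) == 109,
          length(union(pkn_edges$source, pkn_edges$target)) == 63,
          setequal(pkn_nodes$node, union(pkn_edges$source, pkn_edges$target)),
          nrow(pkn_nodes) == 63,
          setequal(final_nodes$node, union(final_edges$source, final_edges$target)))

hdr_final <- c(
  "# PC12 NGF differentiation: final Boolean model (32 nodes, 52 edges).",
  "# Synthetic reconstruction from published main-text statements (fixed-edge",
  "# list, pathway and feedback descriptions); the original supplementary",
  "# transition tables were not available for transcription.",
  "# Columns: source<TAB>sign<TAB>target<TAB>fixed")
hdr_pkn <- c(
  "# PC12 NGF differentiation: prior-knowledge network (63 nodes, 109 edges).",
  "# Synthetic reconstruction from published main-text statements; see the",
  "# package methods vignette for transcription precedence.",
  "# Columns: source<TAB>sign<TAB>target<TAB>fixed")

write_sif_file <- function(edges, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(header, con)
  writeLines(paste(edges$source, edges$sign, edges$target, edges$fixed,
                   sep = "\t"), con)
  close(con)
}
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_sif_file(final_edges, "inst/extdata/pc12_final.sif", hdr_final)
write_sif_file(pkn_edges, "inst/extdata/pc12_pkn.sif", hdr_pkn)
writeLines(c("# Transition rules of the final PC12 Boolean model.",
             "# NGF is an input node (self-maintaining unless clamped).",
             final_rules), "inst/extdata/pc12_final_rules.txt")
write.table(final_nodes, "inst/extdata/pc12_final_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pkn_nodes, "inst/extdata/pc12_pkn_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("fixtures written\n")
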