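# Generates the packaged extdata:
#   synthetic_rCRS.fasta  -- deterministic synthetic stand-in for the 16,569-bp
#                            human mtDNA reference (real sequence not shippable);
#                            real reference bases are pinned at every position the
#                            fixtures and tests depend on.
#   mt_gene_table.tsv     -- standard public rCRS gene annotation.
#   haplogroup_tree_fixture.tsv -- bundled haplogroup-definition tree.
# Run from the repo root: Rscript data-raw/make_extdata.R

suppressPackageStartupMessages(library(Biostrings))

L <- 16569L
set.seed(16569L)
bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.31, 0.31, 0.13, 0.25))

pin <- function(at, s) {
  stopifnot(length(at) == nchar(s))
  bases[at] <<- strsplit(s, "")[[1]]
}

# Real rCRS bases at positions the package's fixtures and tests touch.
pin(73L, "A"); pin(150L, "C"); pin(152L, "T"); pin(263L, "A"); pin(279L, "T")
pin(303:315, "CCCCCCCTCCCCC")          # poly-C tract, 310T
pin(489L, "T")
pin(513:524, "GCACACACACAC")           # AC repeat region
pin(750L, "A"); pin(1438L, "A"); pin(1719L, "G"); pin(2706L, "A")
pin(4769L, "A"); pin(4883L, "C")
pin(5173:5180, "TTAGCTAA")             # AluI AGCT overlapping anchor 5176; 5178=T
pin(6260L, "G"); pin(7028L, "C")
pin(8272:8289, "CCCCCTCTACCCCCTCTA")   # tandem 9-bp repeat (CCCCCTCTA x2)
pin(8701L, "A"); pin(8860L, "A")
pin(9540L, "T")
pin(10398:10400, "ACC")                # ND3 codon 114 start; 10398A, 10400C
pin(10873L, "T")
pin(12404:12409, "GTTAAC")             # HpaI site at anchor 12406
pin(12705L, "C")
pin(14766L, "C"); pin(14783L, "T"); pin(15043L, "G"); pin(15301L, "G")
pin(15326L, "A")
pin(16172L, "T")
pin(16182:16183, "AA")
pin(16184:16193, "CCCCCTCCCC")         # 16189T inside the HVS-I C tract
pin(16223L, "C"); pin(16290L, "C"); pin(16311L, "T"); pin(16319L, "G")
pin(16519L, "T")

dna <- DNAStringSet(paste(bases, collapse = ""))
names(dna) <- "synthetic_rCRS synthetic stand-in for the 16569 bp human mtDNA reference"
writeXStringSet(dna, "inst/extdata/synthetic_rCRS.fasta", width = 70L)

# Standard rCRS gene annotation (public knowledge; coordinates 1-based inclusive).
gene_tab <- "feature\tstart\tend\tkind\tstrand
tRNA-Phe\t577\t647\ttRNA\tH
12S-rRNA\t648\t1601\trRNA\tH
tRNA-Val\t1602\t1670\ttRNA\tH
16S-rRNA\t1671\t3229\trRNA\tH
tRNA-Leu-UUR\t3230\t3304\ttRNA\tH
ND1\t3307\t4262\tprotein\tH
tRNA-Ile\t4263\t4331\ttRNA\tH
tRNA-Gln\t4329\t4400\ttRNA\tL
tRNA-Met\t4402\t4469\ttRNA\tH
ND2\t4470\t5511\tprotein\tH
tRNA-Trp\t5512\t5579\ttRNA\tH
tRNA-Ala\t5587\t5655\ttRNA\tL
tRNA-Asn\t5657\t5729\ttRNA\tL
tRNA-Cys\t5761\t5826\ttRNA\tL
tRNA-Tyr\t5826\t5891\ttRNA\tL
CO1\t5904\t7445\tprotein\tH
tRNA-Ser-UCN\t7446\t7514\ttRNA\tL
tRNA-Asp\t7518\t7585\ttRNA\tH
CO2\t7586\t8269\tprotein\tH
tRNA-Lys\t8295\t8364\ttRNA\tH
ATP8\t8366\t8572\tprotein\tH
ATP6\t8527\t9207\tprotein\tH
CO3\t9207\t9990\tprotein\tH
tRNA-Gly\t9991\t10058\ttRNA\tH
ND3\t10059\t10404\tprotein\tH
tRNA-Arg\t10405\t10469\ttRNA\tH
ND4L\t10470\t10766\tprotein\tH
ND4\t10760\t12137\tprotein\tH
tRNA-His\t12138\t12206\ttRNA\tH
tRNA-Ser-AGY\t12207\t12265\ttRNA\tH
tRNA-Leu-CUN\t12266\t12336\ttRNA\tH
ND5\t12337\t14148\tprotein\tH
ND6\t14149\t14673\tprotein\tL
tRNA-Glu\t14674\t14742\ttRNA\tL
CYB\t14747\t15887\tprotein\tH
tRNA-Thr\t15888\t15953\ttRNA\tH
tRNA-Pro\t15956\t16023\ttRNA\tL
"
writeLines(gene_tab, "inst/extdata/mt_gene_table.tsv", sep = "")

# Bundled haplogroup-definition tree. Motifs for the newly described clades
# M54a, M55b and M84b are the published defining mutations; motifs of the other
# basal clades (marked SYNTHETIC PLACEHOLDER) stand in for definitions that are
# only available in unpublished supplementary material.
tree_tab <- "# Haplogroup definition fixture.
# Columns: Name, Parent, Motif (space-separated tokens, '@' = back mutation), Ancestry.
# Motifs for M24, M45, M54, M55, M82, M83, M84, M84a, M90 and M91 are SYNTHETIC
# PLACEHOLDERS (full definitions live in unavailable supplementary data).
Name\tParent\tMotif\tAncestry
ROOT\t\t\t
M\tROOT\t489 10400 14783 15043 16223\t
N\tROOT\t16223 10398\t
R\tN\t12705\t
HV\tR\t73 14766\tWestEurasian
B\tR\t8281-8289d 16189\tEastEurasian
A\tN\t235 663 1736 4824 16290 16319\tEastEurasian
D4\tM\t4883 5178A 3010 8414 14668\tEastEurasian
M45\tM\t8618 16051 16356\tSouthAsian
M24\tM\t14502 16234\tOther
M54\tM\t8155 16357\tOther
M54a\tM54\t12414 16189\tOther
M55\tM\t12561 15930\tOther
M55b\tM55\t16172 7972 5564 1719 1047 373 10398\tOther
M82\tM\t5302 16148\tOther
M83\tM\t9962 16260\tOther
M84\tM\t6305 16327\tOther
M84a\tM84\t1524 16215\tOther
M84b\tM84\t16311 6260 279 152 150\tOther
M90\tM\t6756 16164\tOther
M91\tM\t5460 16203\tOther
"
writeLines(tree_tab, "inst/extdata/haplogroup_tree_fixture.tsv", sep = "")

cat("extdata written\n")
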