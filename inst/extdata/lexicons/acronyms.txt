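# fixture known bio-acronym list (case-sensitive lookup)
DNA
RNA
mRNA
tRNA
rRNA
PCR
RT-PCR
GO
SNP
EST
ORF
UTR
CDS
BP
MF
CC
HMM
SVM
ANOVA
ROC
AUC
FDR
GWAS
QTL
CNV
ChIP
NGS
BMI
HIV
ATP
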