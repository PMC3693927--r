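# fixture Bioconductor package-name list (one per line)
affy
limma
aCGH
graph
ROC
edgeR
DESeq
DESeq2
GOstats
biomaRt
Biostrings
GenomicRanges
marray
vsn
siggenes
multtest
annotate
genefilter
simpleaffy
makecdfenv
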