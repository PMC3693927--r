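# fixture resource dictionary: variant<TAB>canonical (canonical optional)
BLAST	BLAST
BLASTP	BLAST
BLASTN	BLAST
PSI-BLAST	PSI-BLAST
ClustalW	ClustalW
ClustalX	ClustalW
Clustal W	ClustalW
MUSCLE	MUSCLE
MAFFT	MAFFT
T-Coffee	T-Coffee
MUMmer	MUMmer
Vmatch	Vmatch
Gene Ontology	Gene Ontology
GenBank	GenBank
EMBL	EMBL
UniProt	UniProt
Swiss-Prot	Swiss-Prot
TrEMBL	TrEMBL
RefSeq	RefSeq
Ensembl	Ensembl
PDB	PDB
SCOP	SCOP
CATH	CATH
Pfam	Pfam
InterPro	InterPro
PROSITE	PROSITE
KEGG	KEGG
Reactome	Reactome
GEO	GEO
ArrayExpress	ArrayExpress
PubMed	PubMed
MEDLINE	MEDLINE
MeSH	MeSH
Cytoscape	Cytoscape
Galaxy	Galaxy
Taverna	Taverna
BioPerl	BioPerl
Biopython	Biopython
BioJava	BioJava
Bioconductor	Bioconductor
R	R
MySQL	MySQL
PostgreSQL	PostgreSQL
PhyML	PhyML
RAxML	RAxML
MrBayes	MrBayes
PAUP	PAUP
PolyPhen	PolyPhen
SIFT	SIFT
HMMER	HMMER
SAMtools	SAMtools
Bowtie	Bowtie
TopHat	TopHat
dbSNP	dbSNP
OMIM	OMIM
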