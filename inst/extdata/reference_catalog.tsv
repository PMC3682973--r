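# Characterized 4-epimerase reference proteins anchoring clades A-D,
# compiled from the published clade descriptions. Accession numbers are
# catalogued in the original supplementary material and are not
# redistributed here; the column is left empty.
name	organism	clade	function	accession
Gne_YenterocoliticaO8	Yersinia enterocolitica O:8	A	UDP-GlcNAc 4-epimerase (also UDP-Glc)	
Gne2_EcoliO86	Escherichia coli O86	A	UDP-GlcNAc 4-epimerase	
GalE_Ecoli	Escherichia coli K-12	A	UDP-Glc 4-epimerase	
GalE_Human	Homo sapiens	A	UDP-Glc 4-epimerase (also UDP-GlcNAc)	
WbpP_PaeruginosaO6	Pseudomonas aeruginosa O6	B	UDP-GlcNAcA 4-epimerase	
WbgU_Pshigelloides	Plesiomonas shigelloides O17	B	UDP-GlcNAcA 4-epimerase	
TviC_Senterica	Salmonella enterica (Vi antigen)	B	UDP-GlcNAcA 4-epimerase (previously viaC)	
WbpV_PaeruginosaO6	Pseudomonas aeruginosa O6	C	putative UDP-4-keto-sugar reductase	
Gnu_EcoliO157	Escherichia coli O157	D	UndPP-GlcNAc 4-epimerase	
Gne1_YpseudotuberculosisO6	Yersinia pseudotuberculosis O:6	D	UndPP-GlcNAc 4-epimerase	
Gne1_YpseudotuberculosisO7	Yersinia pseudotuberculosis O:7	D	UndPP-GlcNAc 4-epimerase	
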