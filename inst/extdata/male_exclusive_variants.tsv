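#CHROM	POS	Gene_ID	Gene_Name	CytoBand	Avsnp150	Category	REF	ALT	Gene_Full_Name	p-Value
chr1	114515717	ENSG00000163349	HIPK1	1p13.2	rs2358996	synonymous_variant	G	A	homeodomain interactingprotein kinase 1	0.0286
chr1	234573357	ENSG00000059588	TARBP1	1q42.2	rs2273875	intron_variant	G	C	TAR (HIV-1) RNA binding protein 1	0.0286
chr1	237817784	ENSG00000198626	RYR2	1q43	rs669375	intron_variant	A	G	ryanodine receptor 2	0.0286
chr2	31397696	ENSG00000214711	CAPN14	2p23.1	rs10180369	intron_variant	G	C	calpain 14	0.0286
chr2	31397727	ENSG00000214711	CAPN14	2p23.1	rs10180369	intron_variant	T	C	calpain 14	0.0286
chr2	31399659	ENSG00000214711	CAPN14	2p23.1	rs6720151	intron_variant	T	C	calpain 14	0.0286
chr2	31399751	ENSG00000214711	CAPN14	2p23.1	rs6720254	intron_variant	T	G	calpain 14	0.0286
chr2	31399988	ENSG00000214711	CAPN14	2p23.1	rs4592896	non-synonymous SNV	C	T	calpain 14	0.0286
chr2	31400039	ENSG00000214711	CAPN14	2p23.1	rs4516476	intron_variant	A	G	calpain 14	0.0286
chr2	31400502	ENSG00000214711	CAPN14	2p23.1	rs13421721	intron_variant	A	C	calpain 14	0.0286
chr2	31400510	ENSG00000214711	CAPN14	2p23.1	rs1443707	intron_variant	G	A	calpain 14	0.0286
chr2	31400722	ENSG00000214711	CAPN14	2p23.1	rs1443706	intron_variant	G	A	calpain 14	0.0286
chr2	31400867	ENSG00000214711	CAPN14	2p23.1	rs1373216	intron_variant	T	C	calpain 14	0.0286
chr2	31401499	ENSG00000214711	CAPN14	2p23.1	rs28684727	intron_variant	G	A	calpain 14	0.0286
chr2	31403947	ENSG00000214711	CAPN14	2p23.1	rs2028678	intron_variant	G	A	calpain 14	0.0286
chr2	174946760	ENSG00000138430	OLA1	2q31.1	rs11558990	non-synonymous SNV	T	C	Obg-like ATPase 1	0.0286
chr2	174988189	ENSG00000138430	OLA1	2q31.1	rs10930639	intron_variant	C	T	Obg-like ATPase 1	0.0286
chr2	175199895	ENSG00000231453	AC018470.4	2q31.1	rs3856434	downstream_gene_variant	G	A	Sp9 transcription factor	0.0286
chr3	42772038	ENSG00000244607	CCDC13	3p22.1	rs12495805	non-synonymous SNV	A	T	coiled-coil domain containing 13	0.0286
chr3	124646594	ENSG00000173702	MUC13	3q21.2	rs4679394	non-synonymous SNV	A	G	mucin 13, cell-surface-associated	0.0286
chr3	190967779	ENSG00000188729	OSTN	3q28	rs2034771	intron_variant	A	G	osteocrin	0.0286
chr4	91645179	ENSG00000184305	CCSER1	4q22.1	rs62314447	intron_variant	A	T	multimerin 1	0.0286
chr6	47253631	ENSG00000146072	TNFRSF21	6p12.3	rs11758366	intron_variant	A	G	tumor necrosis factor receptor superfamily member 21	0.0286
chr7	3861353	ENSG00000146555	SDK1	7p22.2	rs6943646	intron_variant	C	G	sidekick cell adhesion molecule 1	0.0286
chr7	72396170	ENSG00000196313	POM121	7q11.23	rs782134793	intron_variant	GCGCCGCGCTCCCCAC	G	POM121 transmembrane nucleoporin	0.0286
chr7	140036999	ENSG00000157800	SLC37A3	7q34	rs4332050	intron_variant	G	A	solute carrier family 37 member 3	0.0286
chr7	140044979	ENSG00000157800	SLC37A3	7q34	rs6974016	upstream_gene_variant	C	T	solute carrier family 37 member 3	0.0286
chr9	100889340	ENSG00000106789	CORO2A	9q22.33	rs942165	intron_variant	G	T	coronin 2A	0.0286
chr10	51549314	ENSG00000138294	MSMB	10q11.23	rs12770171	upstream_gene_variant	C	T	translocase of inner mitochondrial membrane 23 homolog B	0.0286
chr10	129179426	ENSG00000150760	DOCK1	10q26.2	rs7099958	intron_variant	T	C	dedicator of cytokinesis 1	0.0286
chr11	3078536	ENSG00000110619	CARS	11p15.4	rs4758463	intron_variant	C	G	cysteinyl-tRNA synthetase	0.0286
chr12	122079189	ENSG00000182500	ORAI1	12q24.31	rs3741595	synonymous_variant	C	T	ORAI calcium release-activated calciummodulator 1	0.0286
chr12	131623850	ENSG00000111452	ADGRD1	12q24.33	rs35160436	non-synonymous SNV	A	AC	adhesion G protein-coupled receptor D1	0.0286
chr13	113793849	ENSG00000126218	F10	13q34	rs3211770	upstream_gene_variant	G	A	coagulation factor X	0.0286
chr14	35228090	ENSG00000198604	BAZ1A	14q13.1	rs61981202	intron_variant	G	A	bromodomain adjacent to zinc finger domain 1A	0.0286
chr14	35237874	ENSG00000198604	BAZ1A	14q13.1	rs61981228	downstream_gene_variant	C	A	bromodomain adjacent to zinc finger domain 1A	0.0286
chr14	35483882	ENSG00000100883	SRP54	14q13.2	rs13379372	sequence_feature	A	C	signal recognition particle 54kDa	0.0286
chr14	35492299	ENSG00000100883	SRP54	14q13.2	rs4982254	upstream_gene_variant	AG	A	signal recognition particle 54kDa	0.0286
chr14	35492301	ENSG00000100883	SRP54	14q13.2	rs80306194	upstream_gene_variant	CTTGTTATTAGTTAACAG	C	signal recognition particle 54kDa	0.0286
chr14	35497285	ENSG00000100883	SRP54	14q13.2	rs78609489	intron_variant	T	C	signal recognition particle 54kDa	0.0286
chr16	2906934	ENSG00000263325	LA16c-325D7.1	16p13.3	rs732532	upstream_gene_variant	G	A	protease, serine 22	0.0286
chr16	3021417	ENSG00000127564	PKMYT1	16p13.3	rs79505645	upstream_gene_variant	G	T	progestin and adipoQ receptor family member IV	0.0286
chr16	15126890	ENSG00000179889	PDXDC1	16p13.11	rs12926897	upstream_gene_variant	C	T	pyridoxal-dependent decarboxylase domain containing 1	0.0286
chr16	15850204	ENSG00000133392	MYH11	16p13.11	rs2272554	synonymous_variant	A	G	myosin, heavy chain 11, smooth muscle	0.0286
chr16	15853596	ENSG00000133392	MYH11	16p13.11	rs2280764	intron_variant	C	G	myosin, heavy chain 11, smooth muscle	0.0286
chr16	16138322	ENSG00000103222	ABCC1	16p13.11	rs246221	synonymous_variant	T	C	ATP binding cassette subfamily C member 1	0.0286
chr16	16139714	ENSG00000103222	ABCC1	16p13.11	rs35587	synonymous_variant	T	C	ATP binding cassette subfamily C member 1	0.0286
chr16	16139878	ENSG00000103222	ABCC1	16p13.11	rs35588	splice_region_variantand intron_variant	A	G	ATP binding cassette subfamily C member 1	0.0286
chr17	57951973	ENSG00000108423	TUBD1	17q23.1	rs2250526	synonymous_variant	G	A	tubulin delta 1	0.0286
chr17	57992145	ENSG00000241913	RP5-1073F15.1	17q23.1	rs3066247	downstream_gene_variant	TATC	T	ribosomal protein S6 kinase B1	0.0286
chr17	58037374	ENSG00000189050	RNFT1	17q23.1	rs12600680	upstream_gene_variant	T	C	ring finger protein, transmembrane 1	0.0286
chr17	58042126	ENSG00000189050	RNFT1	17q23.1	rs76419616	upstream_gene_variant	T	C	TBC1D3P1-DHX40P1 readthrough, transcribed pseudogene	0.0286
chr19	33882222	ENSG00000124299	PEPD	19q13.11	rs17569	synonymous_variant	G	A	peptidase D	0.0286
chr22	23487533	ENSG00000100228	RAB36	22q11.22	rs1476441	5_prime_UTR_variant	C	T	RAB36, member RAS oncogene family	0.0286
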