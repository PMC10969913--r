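#CHROM	POS	Gene_ID	Gene_Name	CytoBand	Avsnp150	Category	REF	ALT	Gene_Full_Name	p-Value
chr1	17085589	ENSG00000186715	MST1L	1p36.13	rs3863807	upstream_gene_variant	AGCGCTG	A	macrophage stimulating 1-like	0.0286
chr1	26487940	ENSG00000197245	FAM110D	1p36.11	rs3748856	missense_variant	A	G	family with sequence similarity 110 member D	0.0286
chr1	26496455	ENSG00000142684	ZNF593	1p36.11	rs2232648	5_prime_UTR_premature_start_codon_gain_variant	C	T	zinc finger protein 593	0.0286
chr1	154941593	ENSG00000160691	SHC1	1q21.3	rs4845401	upstream_gene_variant	C	G	SHC (Src homology 2 domain containing) transforming protein 1	0.0286
chr1	182509292	ENSG00000121446	RGSL1	1q25.3	rs266531	intron_variant	A	G	regulator of G-protein signaling like 1	0.0286
chr1	182509617	ENSG00000121446	RGSL1	1q25.3	rs3911280	intron_variant	C	A	regulator of G-protein signaling like 1	0.0286
chr1	182517357	ENSG00000121446	RGSL1	1q25.3	rs6657620	intron_variant	G	C	regulator of G-protein signaling like 1	0.0286
chr1	232172374	ENSG00000162946	DISC1	1q42.2	rs17773715	intron_variant	G	A	TSNAX-DISC1 readthrough (NMD candidate)	0.0286
chr2	55176112	ENSG00000214595	EML6	2p16.1	rs13394146	intron_variant	C	T	echinoderm microtubule associated protein like 6	0.0286
chr2	84668155	ENSG00000163541	SUCLG1	2p11.2	rs115384987	downstream_gene_variant	T	C	succinate-CoA ligase, α subunit	0.0286
chr2	127808226	ENSG00000136717	BIN1	2q14.3	rs2071270	intron_variant	A	T	bridging integrator 1	0.0286
chr2	127821085	ENSG00000136717	BIN1	2q14.3	rs2071268	intron_variant	C	T	bridging integrator 1	0.0286
chr2	202526366	ENSG00000082126	MPP4	2q33.1	rs62193397	downstream_gene_variant	G	A	membrane protein, palmitoylated 4	0.0286
chr3	32933360	ENSG00000206557	TRIM71	3p22.3	rs372794141	3_prime_UTR_variant	C	T,CTT	tripartite motif containing 71, E3 ubiquitin protein ligase	0.0286
chr3	57431721	ENSG00000559559	DNAH12	3p14.3	rs372891308	missense_variant	AAAAT	A	dynein axonemal heavy chain 12	0.0286
chr4	110896050	ENSG00000138798	EGF	4q25	rs2067004	sequence_feature	A	C	epidermal growth factor	0.0286
chr5	40980086	ENSG00000112936	C7	5p13.1	rs1450664	splice_region_variantand intron_variant	T	C	complement component 7	0.0286
chr5	40981689	ENSG00000112936	C7	5p13.1	rs1061429	3_prime_UTR_variant	C	A	complement component 7	0.0286
chr6	25914801	ENSG00000112337	SLC17A2	6p22.2	rs62394272	missense_variant	G	A	solute carrier family 17 member 2	0.0286
chr6	25914901	ENSG00000112337	SLC17A2	6p22.2	rs2071298	splice_region_variantand intron_variant	G	A	solute carrier family 17 member 2	0.0286
chr6	25916979	ENSG00000112337	SLC17A2	6p22.2	rs1865760	synonymous_variant	C	T	solute carrier family 17 member 2	0.0286
chr6	25918688	ENSG00000112337	SLC17A2	6p22.2	rs1865760	intron_variant	G	A	solute carrier family 17 member 2	0.0286
chr6	25924158	ENSG00000112337	SLC17A2	6p22.2	rs1540273	intron_variant	T	C	solute carrier family 17 member 2	0.0286
chr6	25925823	ENSG00000112337	SLC17A2	6p22.2	rs7770139	intron_variant	A	G	solute carrier family 17 member 2	0.0286
chr6	26027135	ENSG00000124529	HIST1H4B	6p22.2	rs3752420	3_prime_UTR_variant	G	A	histone cluster 1, H4b	0.0286
chr6	26027433	ENSG00000124529	HIST1H4B	6p22.2	rs3752419	synonymous_variant	G	A	histone cluster 1, H4b	0.0286
chr6	26087856	ENSG00000010704	HFE	6p22.2	rs2858993	intron_variant	T	A	homeostatic iron regulator	0.0286
chr6	71011831	ENSG00000112280	COL9A1	6q13	rs2242589	intron_variant	C	T	collagen type IX α 1	0.0286
chr6	99819556	ENSG00000132423	COQ3	6q16.2	rs4574651	downstream_gene_variant	C	T	coenzyme Q3 methyltransferase	0.0286
chr6	152679729	ENSG00000131018	SYNE1	6q25.2	rs9478326	intron_variant	G	A	spectrin repeat containing nuclear envelope 1	0.0286
chr7	142498813	ENSG00000211772	TRBC2	7q34	rs1042955	synonymous_variant	G	A	T cell receptor β constant 2	0.0286
chr8	103301555	ENSG00000104517	UBR5	8q22.3	rs2168689	intron_variant	T	C	ubiquitin protein ligase E3 component n-recognin 5	0.0286
chr9	107593182	ENSG00000165029	ABCA1	9q31.1	rs4743763	intron_variant	A	T	ATP binding cassette subfamily A member 1	0.0286
chr10	47701275	ENSG00000198250	ANTXRL	10q11.22	rs10906952	synonymous SNV	G	A	anthrax toxin receptor-like	0.0286
chr10	126480381	ENSG00000203791	METTL10	10q26.13	rs965484	missense_variant	C	T	EEF1A lysine methyltransferase 2	0.0286
chr11	72309540	ENSG00000186642	PDE2A	11q13.4	rs4943939	upstream_gene_variant	C	T	phosphodiesterase 2A	0.0286
chr12	9750669	ENSG00000111796	KLRB1	12p13.31	rs1135816	nonsynonymous SNV	A	G	killer cell lectin like receptor B1	0.0286
chr12	53880122	ENSG00000139625	MAP3K12	12q13.13	rs3816806	upstream_gene_variant	T	C	mitogen-activated protein kinase 12	0.0286
chr12	53896984	ENSG00000139546	TARBP2	12q13.13	rs2280448	3_prime_UTR_variant	G	A	TAR (HIV-1) RNA binding protein 2	0.0286
chr12	56865338	ENSG00000135423	GLS2	12q13.3	rs2657879	nonsynonymous SNV	A	G	glutaminase 2	0.0286
chr12	56866334	ENSG00000135517	MIP	12q13.3	rs2657880	upstream_gene_variant	T	A	major intrinsic factor of lens fiber	0.0286
chr12	88448328	ENSG00000133641	C12orf29	12q21.32	rs17418744	downstream_gene_variant	T	A	centrosomal protein 290kDa	0.0286
chr12	119419632	ENSG00000139767	SRRM4	12q24.23	rs1568924	5_prime_UTR_variant	C	T	serine/arginine repetitive matrix 4	0.0286
chr14	65414976	ENSG00000139998	RAB15	14q23.3	rs11540871	3_prime_UTR_variant	C	T	RAB15, member RAS oncogene family	0.0286
chr14	71215822	ENSG00000006432	MAP3K9	14q24.2	rs79518608	downstream_gene_variant	T	C	mitogen-activated protein kinase 9	0.0286
chr14	105268104	ENSG00000179627	ZBTB42	14q32.33	rs10141867	synonymous_variant	G	A	zinc finger and BTB domain containing 42	0.0286
chr14	107211211	ENSG00000211976	IGHV3-73	14q32.33	rs2073668	synonymous_variant	G	A	immunoglobulin heavy variable 3-73	0.0286
chr16	57075379	ENSG00000140853	NLRC5	16q13	rs35622257	missense_variant	G	GT	NLR family, CARD domain containing 5	0.0286
chr16	57080528	ENSG00000140853	NLRC5	16q13	rs289723	nonsynonymous SNV	C	A	NLR family, CARD domain containing 5	0.0286
chr17	12832063	ENSG00000006740	ARHGAP44	17p12	rs1317990	intron_variant	G	T	Rho GTPase activating protein 44	0.0286
chr17	76867017	ENSG00000035862	TIMP2	17q25.3	rs2277698	synonymous_variant	C	T	TIMP metallopeptidase inhibitor 2	0.0286
chr18	56202768	ENSG00000198796	ALPK2	18q21.32	rs3809983	nonsynonymous SNV	C	A	α kinase 2	0.0286
chr18	56203120	ENSG00000198796	ALPK2	18q21.32	rs3809981	synonymous_variant	C	T	α kinase 2	0.0286
chr18	77724726	ENSG00000226742	HSBP1L1	18q23	rs8095764	5_prime_UTR_variant	A	C	heat shock factor binding protein 1-like 1	0.0286
chr19	17091368	ENSG00000160111	CPAMD8	19p13.11	rs8103646	synonymous_variant	T	G	C3- and PZP-like, α-2-macroglobulin domain containing 8	0.0286
chr19	39138608	ENSG00000130402	ACTN4	19q13.2	rs2303040	upstream_gene_variant	T	C	actinin α 4	0.0286
chr19	39196745	ENSG00000130402	ACTN4	19q13.2	rs3745859	synonymous SNV	C	T	actinin α 4	0.0286
chr19	39215333	ENSG00000130402	ACTN4	19q13.2	rs3786851	upstream_gene_variant	C	T	actinin α 4	0.0286
chr19	55644442	ENSG00000105048	TNNT1	19q13.42	rs891186	downstream_gene_variant	G	A	troponin T1, slow skeletal type	0.0286
chr20	1617069	ENSG00000089012	SIRPG	20p13	rs2277761	synonymous_variant	A	G	signal regulatory protein γ	0.0286
chr22	29834766	ENSG00000128250	RFPL1	22q12.2	rs465736	5_prime_UTR_variant	A	G	RFPL1 antisense RNA 1	0.0286
chr22	50906518	ENSG00000100241	SBF1	22q13.33	rs1983679	upstream_gene_variant	G	A	SET binding factor 1	0.0286
chr22	50906917	ENSG00000100241	SBF1	22q13.33	rs9616852	upstream_gene_variant	C	A	SET binding factor 1	0.0286
chrX	149937404	ENSG00000102181	CD99L2	Xq28	rs41311690	3_prime_UTR_variant	T	C	CD99 molecule-like 2	0.0286
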