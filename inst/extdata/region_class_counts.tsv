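region_class	snv_count	indel_count
downstream	580	72
exonic	35000	733
exonic;splicing	17	4
intergenic	3941	371
intronic	79259	10837
ncRNA_exonic	3011	252
ncRNA_intronic	4444	550
ncRNA_splicing	8	0
splicing	111	47
upstream	1228	115
upstream;downstream	115	5
UTR3	4504	687
UTR5	2730	247
UTR5;UTR3	13	5
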