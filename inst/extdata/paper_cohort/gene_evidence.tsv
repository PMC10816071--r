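gene	is_mtDNA	sfari_rank	syndromic	autdb_stars	de_novo_cadd20_in_other_ndd	variant_reported_in_asd_case	asd_cnv_count	asd_like_animal_model	lof_intolerant	fxs_gene_asd_enriched	brain_exon_dnm_accumulation	direct_link_to_direct_gene	linked_other_ndd_cadd20	asd_pathway_member	predominately_non_nervous	ar_only_disease_gene
EHMT1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
KCNB1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
UBE3A	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SPEN	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ANKRD11	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ANKFN1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TCF20	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RERE	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ZNF292	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
FRMPD4	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RELN	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CACNA1A	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RIMS1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SCN2A	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ASH1L	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
DEAF1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
PAH	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
DYNC1H1	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TSC2	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
KMT2E	0	1	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GRB10	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GABRA1	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
AGO3	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
OTUD7A	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
FAN1	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TRPM1	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ARHGAP11B	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CHRNA7	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GGNBP2	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RIF1	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SYND2	0	2	0	.	0	0	0	0	0	0	0	0	0	0	0	0
COL4A1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TRPM2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MTMR4	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
USP20	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GRIK1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CEP170	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
NUP210	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
KRAS	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
YTHDF1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
STAT1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GOLGB1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SP8	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
HSPA1A	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
PGAM5	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SLC41A2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
OCM	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
PRODH	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
IVD	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
THOC2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SLC1A4	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
USP9X	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
NLGN4X	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
EIF3F	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SYND1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RYR2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CDH15	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TRAP1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CHL1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
RIC1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CLPX	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
POLRMT	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SCN10A	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
FLNA	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SCN9A	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CPT2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CIC	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
POLA1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SETD1B	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MTHFR	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
HSPG2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
CUX2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
IMMP2L	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
ADAMTS18	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SCN4A	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
KCND2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
IGHG2	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SORCS3	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
DOCK8	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
TBC1D8B	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
GBE1	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
SHROOM4	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
PRKCA	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
FANCL	0	3	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-CO1	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-TW	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-ND3	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-CYB	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-TC	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
MT-CO3	1	.	0	.	0	0	0	0	0	0	0	0	0	0	0	0
POGLUT3	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
BRPF3	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
GTF2A1	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
TMEM184B	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1Q1	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N1	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N2	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N3	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N4	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N5	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N6	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N7	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
SYNB1N8	0	.	0	.	0	0	0	0	0	0	0	1	0	0	0	0
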