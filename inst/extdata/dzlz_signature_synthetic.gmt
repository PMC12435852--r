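DZ_up	synthetic_standin_dz_spatial_signature	AICDA	CXCR4	FOXO1	MKI67	TOP2A	PLK1	PLK4	EZH2	CCNB1	CCNB2	CCNA2	CDK1	CDC20	BUB1	BUB1B	AURKA	AURKB	E2F1	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	PCNA	RRM2	TYMS	POLA1	POLE	H2AFX	CHEK1	ATR	BRCA1	BRCA2	RAD51	FANCI	FANCD2	TK1	TTK	KIF11	CENPF	NUSAP1	ASPM	ESPL1	NCAPG	SMC2	SMC4	UHRF1	DNMT1	EXO1	MSH2	SPC24	SPC25	NDC80	CDC6	CDT1	GINS1	GINS2	ORC1	ORC6	CLSPN	TIMELESS	TIPIN	RPA3	LIG1	FEN1	DHFR	TCF19	CDC45	WEE1	DZSYN001	DZSYN002	DZSYN003	DZSYN004	DZSYN005	DZSYN006	DZSYN007	DZSYN008	DZSYN009	DZSYN010	DZSYN011	DZSYN012	DZSYN013	DZSYN014	DZSYN015	DZSYN016	DZSYN017	DZSYN018	DZSYN019	DZSYN020	DZSYN021	DZSYN022	DZSYN023	DZSYN024	DZSYN025	DZSYN026	DZSYN027	DZSYN028	DZSYN029	DZSYN030	DZSYN031	DZSYN032	DZSYN033	DZSYN034	DZSYN035	DZSYN036	DZSYN037	DZSYN038	DZSYN039	DZSYN040	DZSYN041	DZSYN042	DZSYN043	DZSYN044	DZSYN045	DZSYN046	DZSYN047	DZSYN048	DZSYN049	DZSYN050	DZSYN051	DZSYN052	DZSYN053	DZSYN054	DZSYN055	DZSYN056	DZSYN057	DZSYN058	DZSYN059	DZSYN060	DZSYN061	DZSYN062	DZSYN063	DZSYN064	DZSYN065	DZSYN066	DZSYN067	DZSYN068	DZSYN069	DZSYN070	DZSYN071	DZSYN072	DZSYN073	DZSYN074	DZSYN075	DZSYN076	DZSYN077	DZSYN078	DZSYN079	DZSYN080	DZSYN081	DZSYN082	DZSYN083	DZSYN084	DZSYN085	DZSYN086	DZSYN087	DZSYN088	DZSYN089	DZSYN090	DZSYN091	DZSYN092	DZSYN093	DZSYN094	DZSYN095	DZSYN096	DZSYN097	DZSYN098	DZSYN099
LZ_up	synthetic_standin_lz_spatial_signature	CD83	CD86	CD40	CXCR5	CD69	BCL2A1	NFKB1	NFKB2	RELB	REL	EGR1	EGR2	EGR3	MYC	CCND2	BATF	ICAM1	SLAMF1	TNF	LTA	LTB	IL4R	STAT6	CIITA	HLA-A	HLA-B	HLA-C	HLA-E	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DPB1	HLA-DQA1	HLA-DQB1	HLA-DMA	HLA-DMB	CD74	B2M	NGFR	CR2	FCER2	TRAF1	BIRC3	CFLAR	JUNB	FOS	FOSB	DUSP2	NR4A1	SEMA7A	GPR183	PSMB9	PSMB8	TAP1	TAP2	NFKBIA	NFKBID	TNFAIP3	CD80	IRF4	PRDM1	SLAMF6	CD84	TNFRSF13B	BANK1	MARCKS	EMP3	LY86	CCR6	GPR18	LZSYN001	LZSYN002	LZSYN003	LZSYN004	LZSYN005	LZSYN006	LZSYN007	LZSYN008	LZSYN009	LZSYN010	LZSYN011	LZSYN012	LZSYN013	LZSYN014	LZSYN015	LZSYN016	LZSYN017	LZSYN018	LZSYN019	LZSYN020	LZSYN021	LZSYN022	LZSYN023	LZSYN024	LZSYN025	LZSYN026	LZSYN027	LZSYN028	LZSYN029	LZSYN030	LZSYN031	LZSYN032	LZSYN033	LZSYN034	LZSYN035	LZSYN036	LZSYN037	LZSYN038	LZSYN039	LZSYN040	LZSYN041	LZSYN042	LZSYN043	LZSYN044	LZSYN045	LZSYN046	LZSYN047	LZSYN048	LZSYN049	LZSYN050	LZSYN051	LZSYN052	LZSYN053	LZSYN054	LZSYN055	LZSYN056	LZSYN057	LZSYN058	LZSYN059	LZSYN060	LZSYN061	LZSYN062	LZSYN063	LZSYN064	LZSYN065	LZSYN066	LZSYN067	LZSYN068	LZSYN069	LZSYN070	LZSYN071	LZSYN072	LZSYN073	LZSYN074	LZSYN075	LZSYN076	LZSYN077	LZSYN078	LZSYN079	LZSYN080	LZSYN081	LZSYN082	LZSYN083	LZSYN084	LZSYN085	LZSYN086	LZSYN087	LZSYN088	LZSYN089	LZSYN090	LZSYN091	LZSYN092	LZSYN093	LZSYN094	LZSYN095	LZSYN096	LZSYN097	LZSYN098	LZSYN099	LZSYN100	LZSYN101	LZSYN102	LZSYN103	LZSYN104	LZSYN105	LZSYN106	LZSYN107	LZSYN108	LZSYN109	LZSYN110	LZSYN111	LZSYN112	LZSYN113	LZSYN114	LZSYN115	LZSYN116	LZSYN117	LZSYN118	LZSYN119	LZSYN120	LZSYN121	LZSYN122	LZSYN123	LZSYN124	LZSYN125	LZSYN126	LZSYN127	LZSYN128	LZSYN129	LZSYN130	LZSYN131
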