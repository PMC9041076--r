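TP53_INACTIVATION	four-gene p53-loss readout	CDC20	PLK1	CENPA	KIF2C
CIN	chromosomal instability (placeholder, editable)	TPX2	PRC1	FOXM1	CDK1	MCM2	H2AFZ	TOP2A	PCNA	UBE2C	MELK	TRIP13	NCAPD2	MCM7	RNASEH2A	RAD51AP1	KIF20A	CDC45	MAD2L1	ESPL1	CCNB2	FEN1	TTK	CCT5	RFC4	ATAD2
PI3K_MTOR_UP	PI3K/mTOR up, padded to 134 with synthetic PMTU symbols	SKP2	AKT1	AKT2	PIK3CA	PIK3CB	MTOR	RPS6KB1	EIF4EBP1	RHEB	RPTOR	RICTOR	PDPK1	SGK1	HIF1A	VEGFA	SREBF1	CCND1	MYC	E2F1	GSK3B	PMTU001	PMTU002	PMTU003	PMTU004	PMTU005	PMTU006	PMTU007	PMTU008	PMTU009	PMTU010	PMTU011	PMTU012	PMTU013	PMTU014	PMTU015	PMTU016	PMTU017	PMTU018	PMTU019	PMTU020	PMTU021	PMTU022	PMTU023	PMTU024	PMTU025	PMTU026	PMTU027	PMTU028	PMTU029	PMTU030	PMTU031	PMTU032	PMTU033	PMTU034	PMTU035	PMTU036	PMTU037	PMTU038	PMTU039	PMTU040	PMTU041	PMTU042	PMTU043	PMTU044	PMTU045	PMTU046	PMTU047	PMTU048	PMTU049	PMTU050	PMTU051	PMTU052	PMTU053	PMTU054	PMTU055	PMTU056	PMTU057	PMTU058	PMTU059	PMTU060	PMTU061	PMTU062	PMTU063	PMTU064	PMTU065	PMTU066	PMTU067	PMTU068	PMTU069	PMTU070	PMTU071	PMTU072	PMTU073	PMTU074	PMTU075	PMTU076	PMTU077	PMTU078	PMTU079	PMTU080	PMTU081	PMTU082	PMTU083	PMTU084	PMTU085	PMTU086	PMTU087	PMTU088	PMTU089	PMTU090	PMTU091	PMTU092	PMTU093	PMTU094	PMTU095	PMTU096	PMTU097	PMTU098	PMTU099	PMTU100	PMTU101	PMTU102	PMTU103	PMTU104	PMTU105	PMTU106	PMTU107	PMTU108	PMTU109	PMTU110	PMTU111	PMTU112	PMTU113	PMTU114
CYTOLYTIC_ACTIVITY	granzyme/perforin mean	GZMA	PRF1
CD8_TCELL	immune population (placeholder)	CD8A	CD8B	GZMK	GZMH	CD3D	CD3E
NK_CELLS	immune population (placeholder)	KLRD1	NCR1	KIR2DL4	NKG7	KLRC1
B_CELLS	immune population (placeholder)	CD19	MS4A1	CD79A	CD79B	BLK
IFN_ALPHA_RESPONSE	interferon alpha response (placeholder subset)	IFI6	IFI27	IFI44	IFI44L	ISG15	MX1	MX2	OAS1	OAS2	OAS3	IFIT1	IFIT3	IRF7	STAT1	STAT2	RSAD2
IFN_GAMMA_RESPONSE	cellular response to interferon gamma (placeholder subset)	HLA-A	HLA-B	HLA-DRA	CXCL9	CXCL10	CXCL11	GBP1	GBP2	IDO1	IRF1
CTNNB1_LIVER_UP	liver-cancer beta-catenin subclass up (placeholder subset)	GLUL	LGR5	TBX3	AXIN2	LECT2	REG3A
TCELL_INFLAMED	T cell-inflamed expression profile	CCL5	CD27	CD274	CD276	CD8A	CMKLR1	CXCL9	CXCR6	HLA-DQA1	HLA-DRB1	HLA-E	IDO1	LAG3	NKG7	PDCD1LG2	PSMB10	STAT1	TIGIT
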