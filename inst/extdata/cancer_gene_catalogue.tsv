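gene	role	source
CTNNB1	ONCOGENE	curated_fixture
PREX2	ONCOGENE	curated_fixture
ROBO1	ONCOGENE	curated_fixture
COL22A1	ONCOGENE	curated_fixture
SRGAP3	ONCOGENE	curated_fixture
SKP2	ONCOGENE	curated_fixture
MYC	ONCOGENE	curated_fixture
CCND1	ONCOGENE	curated_fixture
MET	ONCOGENE	curated_fixture
EGFR	ONCOGENE	curated_fixture
ERBB2	ONCOGENE	curated_fixture
KRAS	ONCOGENE	curated_fixture
NRAS	ONCOGENE	curated_fixture
BRAF	ONCOGENE	curated_fixture
PIK3CA	ONCOGENE	curated_fixture
AKT1	ONCOGENE	curated_fixture
MTOR	ONCOGENE	curated_fixture
TERT	ONCOGENE	curated_fixture
MDM2	ONCOGENE	curated_fixture
MDM4	ONCOGENE	curated_fixture
FGF19	ONCOGENE	curated_fixture
VEGFA	ONCOGENE	curated_fixture
MCL1	ONCOGENE	curated_fixture
CDK4	ONCOGENE	curated_fixture
CDK6	ONCOGENE	curated_fixture
YAP1	ONCOGENE	curated_fixture
NFE2L2	ONCOGENE	curated_fixture
GNAS	ONCOGENE	curated_fixture
IDH1	ONCOGENE	curated_fixture
IDH2	ONCOGENE	curated_fixture
JAK2	ONCOGENE	curated_fixture
KIT	ONCOGENE	curated_fixture
FLT3	ONCOGENE	curated_fixture
ALK	ONCOGENE	curated_fixture
RET	ONCOGENE	curated_fixture
NOTCH2	ONCOGENE	curated_fixture
FGFR1	ONCOGENE	curated_fixture
FGFR2	ONCOGENE	curated_fixture
FGFR3	ONCOGENE	curated_fixture
ABL1	ONCOGENE	curated_fixture
SRC	ONCOGENE	curated_fixture
STAT3	ONCOGENE	curated_fixture
MYCN	ONCOGENE	curated_fixture
HRAS	ONCOGENE	curated_fixture
CARD11	ONCOGENE	curated_fixture
TP53	TSG	curated_fixture
ARID2	TSG	curated_fixture
KEAP1	TSG	curated_fixture
ARID1A	TSG	curated_fixture
ARID1B	TSG	curated_fixture
AXIN1	TSG	curated_fixture
AXIN2	TSG	curated_fixture
RB1	TSG	curated_fixture
PTEN	TSG	curated_fixture
CDKN2A	TSG	curated_fixture
CDKN1A	TSG	curated_fixture
APC	TSG	curated_fixture
SMAD4	TSG	curated_fixture
BAP1	TSG	curated_fixture
VHL	TSG	curated_fixture
NF1	TSG	curated_fixture
NF2	TSG	curated_fixture
STK11	TSG	curated_fixture
TSC1	TSG	curated_fixture
TSC2	TSG	curated_fixture
BRCA1	TSG	curated_fixture
BRCA2	TSG	curated_fixture
ATM	TSG	curated_fixture
ATR	TSG	curated_fixture
CHEK2	TSG	curated_fixture
MLH1	TSG	curated_fixture
MSH2	TSG	curated_fixture
MSH6	TSG	curated_fixture
PMS2	TSG	curated_fixture
FBXW7	TSG	curated_fixture
SETD2	TSG	curated_fixture
PBRM1	TSG	curated_fixture
SMARCA4	TSG	curated_fixture
SMARCB1	TSG	curated_fixture
KMT2C	TSG	curated_fixture
KMT2D	TSG	curated_fixture
CREBBP	TSG	curated_fixture
EP300	TSG	curated_fixture
NCOR1	TSG	curated_fixture
RPS6KA3	TSG	curated_fixture
HNF1A	TSG	curated_fixture
CDH1	TSG	curated_fixture
DNMT3A	TSG	curated_fixture
TET2	TSG	curated_fixture
WT1	TSG	curated_fixture
ALB	OTHER_CANCER_GENE	curated_fixture
APOB	OTHER_CANCER_GENE	curated_fixture
CPS1	OTHER_CANCER_GENE	curated_fixture
IL6ST	OTHER_CANCER_GENE	curated_fixture
JAK1	OTHER_CANCER_GENE	curated_fixture
TSHZ3	OTHER_CANCER_GENE	curated_fixture
EEF1A1	OTHER_CANCER_GENE	curated_fixture
GPATCH4	OTHER_CANCER_GENE	curated_fixture
AHCTF1	OTHER_CANCER_GENE	curated_fixture
ZNF226	OTHER_CANCER_GENE	curated_fixture
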