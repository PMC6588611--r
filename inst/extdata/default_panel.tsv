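# Reconstructed 168-gene hereditary-cancer panel.
# The source publication does not enumerate its gene list; this panel
# contains every gene named in the text with the annotations the text
# implies, padded with standard hereditary-cancer genes. User-replaceable.
symbol	pathway	inheritance	acmg_return	actionable_class
BRCA1	HR	DOMINANT	TRUE	PARPI
BRCA2	HR	DOMINANT	TRUE	PARPI
PALB2	HR	DOMINANT	FALSE	NONE
RAD51	HR	DOMINANT	FALSE	NONE
RAD51B	HR	DOMINANT	FALSE	NONE
RAD51C	HR	DOMINANT	FALSE	NONE
RAD51D	HR	DOMINANT	FALSE	NONE
BAP1	HR	DOMINANT	FALSE	NONE
NBN	HR	DOMINANT	FALSE	NONE
BLM	HR	DOMINANT	FALSE	NONE
WRN	HR	DOMINANT	FALSE	NONE
BARD1	HR	DOMINANT	FALSE	NONE
BRIP1	HR	DOMINANT	FALSE	NONE
XRCC2	HR	DOMINANT	FALSE	NONE
XRCC3	HR	DOMINANT	FALSE	NONE
MRE11	HR	DOMINANT	FALSE	NONE
RAD50	HR	DOMINANT	FALSE	NONE
RECQL	HR	DOMINANT	FALSE	NONE
RECQL4	HR	DOMINANT	FALSE	NONE
RAD54L	HR	DOMINANT	FALSE	NONE
RAD52	HR	DOMINANT	FALSE	NONE
XRCC4	HR	DOMINANT	FALSE	NONE
NBEAL2	HR	DOMINANT	FALSE	NONE
FANCA	FANCONI	DOMINANT	FALSE	NONE
FANCB	FANCONI	DOMINANT	FALSE	NONE
FANCC	FANCONI	DOMINANT	FALSE	NONE
FANCD2	FANCONI	DOMINANT	FALSE	NONE
FANCE	FANCONI	DOMINANT	FALSE	NONE
FANCF	FANCONI	DOMINANT	FALSE	NONE
FANCG	FANCONI	DOMINANT	FALSE	NONE
FANCI	FANCONI	DOMINANT	FALSE	NONE
FANCL	FANCONI	DOMINANT	FALSE	NONE
FANCM	FANCONI	DOMINANT	FALSE	NONE
SLX4	FANCONI	DOMINANT	FALSE	NONE
UBE2T	FANCONI	DOMINANT	FALSE	NONE
ATM	CHECKPOINT	DOMINANT	FALSE	NONE
ATR	CHECKPOINT	DOMINANT	FALSE	NONE
CHEK1	CHECKPOINT	DOMINANT	FALSE	NONE
CHEK2	CHECKPOINT	DOMINANT	FALSE	NONE
TP53	CHECKPOINT	DOMINANT	TRUE	NONE
TOPBP1	CHECKPOINT	DOMINANT	FALSE	NONE
CLSPN	CHECKPOINT	DOMINANT	FALSE	NONE
MDC1	CHECKPOINT	DOMINANT	FALSE	NONE
TP53BP1	CHECKPOINT	DOMINANT	FALSE	NONE
HUS1	CHECKPOINT	DOMINANT	FALSE	NONE
RAD9A	CHECKPOINT	DOMINANT	FALSE	NONE
RAD1	CHECKPOINT	DOMINANT	FALSE	NONE
RAD17	CHECKPOINT	DOMINANT	FALSE	NONE
ATRIP	CHECKPOINT	DOMINANT	FALSE	NONE
XPA	NER	DOMINANT	FALSE	NONE
XPC	NER	DOMINANT	FALSE	NONE
ERCC1	NER	DOMINANT	FALSE	NONE
ERCC2	NER	DOMINANT	FALSE	NONE
ERCC3	NER	DOMINANT	FALSE	NONE
ERCC4	NER	DOMINANT	FALSE	NONE
ERCC5	NER	DOMINANT	FALSE	NONE
ERCC6	NER	DOMINANT	FALSE	NONE
DDB2	NER	DOMINANT	FALSE	NONE
POLH	NER	DOMINANT	FALSE	NONE
MLH1	MMR	DOMINANT	TRUE	IMMUNOTHERAPY
MSH2	MMR	DOMINANT	TRUE	IMMUNOTHERAPY
MSH6	MMR	DOMINANT	TRUE	IMMUNOTHERAPY
PMS2	MMR	DOMINANT	TRUE	IMMUNOTHERAPY
PMS1	MMR	DOMINANT	FALSE	NONE
MLH3	MMR	DOMINANT	FALSE	NONE
MSH3	MMR	DOMINANT	FALSE	NONE
EPCAM	MMR	DOMINANT	FALSE	NONE
APC	OTHER	DOMINANT	TRUE	NONE
PTEN	OTHER	DOMINANT	TRUE	NONE
CDH1	OTHER	DOMINANT	FALSE	NONE
CDKN2A	OTHER	DOMINANT	FALSE	NONE
RB1	OTHER	DOMINANT	TRUE	NONE
SEC23B	OTHER	DOMINANT	FALSE	NONE
SMAD9	OTHER	DOMINANT	FALSE	NONE
FAN1	OTHER	DOMINANT	FALSE	NONE
VHL	OTHER	DOMINANT	TRUE	NONE
STK11	OTHER	DOMINANT	TRUE	NONE
MEN1	OTHER	DOMINANT	TRUE	NONE
MUTYH	OTHER	RECESSIVE	TRUE	NONE
NTHL1	OTHER	RECESSIVE	FALSE	NONE
NF1	OTHER	DOMINANT	FALSE	NONE
NF2	OTHER	DOMINANT	TRUE	NONE
RET	OTHER	DOMINANT	TRUE	NONE
KIT	OTHER	DOMINANT	FALSE	NONE
PDGFRA	OTHER	DOMINANT	FALSE	NONE
SDHA	OTHER	DOMINANT	FALSE	NONE
SDHB	OTHER	DOMINANT	TRUE	NONE
SDHC	OTHER	DOMINANT	TRUE	NONE
SDHD	OTHER	DOMINANT	TRUE	NONE
SDHAF2	OTHER	DOMINANT	TRUE	NONE
TSC1	OTHER	DOMINANT	TRUE	NONE
TSC2	OTHER	DOMINANT	TRUE	NONE
WT1	OTHER	DOMINANT	TRUE	NONE
SMAD4	OTHER	DOMINANT	TRUE	NONE
BMPR1A	OTHER	DOMINANT	TRUE	NONE
PTCH1	OTHER	DOMINANT	FALSE	NONE
SUFU	OTHER	DOMINANT	FALSE	NONE
DICER1	OTHER	DOMINANT	FALSE	NONE
MAX	OTHER	DOMINANT	FALSE	NONE
TMEM127	OTHER	DOMINANT	FALSE	NONE
FH	OTHER	DOMINANT	FALSE	NONE
FLCN	OTHER	DOMINANT	FALSE	NONE
CDC73	OTHER	DOMINANT	FALSE	NONE
CDK4	OTHER	DOMINANT	FALSE	NONE
CDKN1B	OTHER	DOMINANT	FALSE	NONE
CDKN1C	OTHER	DOMINANT	FALSE	NONE
CEBPA	OTHER	DOMINANT	FALSE	NONE
CYLD	OTHER	DOMINANT	FALSE	NONE
DIS3L2	OTHER	DOMINANT	FALSE	NONE
EGFR	OTHER	DOMINANT	FALSE	NONE
EXT1	OTHER	DOMINANT	FALSE	NONE
EXT2	OTHER	DOMINANT	FALSE	NONE
GATA2	OTHER	DOMINANT	FALSE	NONE
HOXB13	OTHER	DOMINANT	FALSE	NONE
HRAS	OTHER	DOMINANT	FALSE	NONE
KRAS	OTHER	DOMINANT	FALSE	NONE
LZTR1	OTHER	DOMINANT	FALSE	NONE
MET	OTHER	DOMINANT	FALSE	NONE
MITF	OTHER	DOMINANT	FALSE	NONE
PALLD	OTHER	DOMINANT	FALSE	NONE
PHOX2B	OTHER	DOMINANT	FALSE	NONE
POLD1	OTHER	DOMINANT	FALSE	NONE
POLE	OTHER	DOMINANT	FALSE	NONE
PRKAR1A	OTHER	DOMINANT	FALSE	NONE
PTPN11	OTHER	DOMINANT	FALSE	NONE
RUNX1	OTHER	DOMINANT	FALSE	NONE
SMARCA4	OTHER	DOMINANT	FALSE	NONE
SMARCB1	OTHER	DOMINANT	FALSE	NONE
SMARCE1	OTHER	DOMINANT	FALSE	NONE
SOS1	OTHER	DOMINANT	FALSE	NONE
TERT	OTHER	DOMINANT	FALSE	NONE
TERC	OTHER	DOMINANT	FALSE	NONE
TMEM43	OTHER	DOMINANT	FALSE	NONE
TSHR	OTHER	DOMINANT	FALSE	NONE
ALK	OTHER	DOMINANT	FALSE	NONE
AXIN2	OTHER	DOMINANT	FALSE	NONE
BUB1B	OTHER	DOMINANT	FALSE	NONE
CBL	OTHER	DOMINANT	FALSE	NONE
CTNNA1	OTHER	DOMINANT	FALSE	NONE
DKC1	OTHER	DOMINANT	FALSE	NONE
ELANE	OTHER	DOMINANT	FALSE	NONE
ETV6	OTHER	DOMINANT	FALSE	NONE
GPC3	OTHER	DOMINANT	FALSE	NONE
JMJD1C	OTHER	DOMINANT	FALSE	NONE
KCNQ1	OTHER	DOMINANT	FALSE	NONE
LMO1	OTHER	DOMINANT	FALSE	NONE
MPL	OTHER	DOMINANT	FALSE	NONE
NRAS	OTHER	DOMINANT	FALSE	NONE
PAX5	OTHER	DOMINANT	FALSE	NONE
PDGFRB	OTHER	DOMINANT	FALSE	NONE
PIK3CA	OTHER	DOMINANT	FALSE	NONE
POT1	OTHER	DOMINANT	FALSE	NONE
PRF1	OTHER	DOMINANT	FALSE	NONE
RAF1	OTHER	DOMINANT	FALSE	NONE
RHBDF2	OTHER	DOMINANT	FALSE	NONE
SBDS	OTHER	DOMINANT	FALSE	NONE
SERPINA1	OTHER	DOMINANT	FALSE	NONE
SH2B3	OTHER	DOMINANT	FALSE	NONE
SH2D1A	OTHER	DOMINANT	FALSE	NONE
SRP72	OTHER	DOMINANT	FALSE	NONE
STAT3	OTHER	DOMINANT	FALSE	NONE
TGFBR1	OTHER	DOMINANT	FALSE	NONE
TGFBR2	OTHER	DOMINANT	FALSE	NONE
TRIM37	OTHER	DOMINANT	FALSE	NONE
WAS	OTHER	DOMINANT	FALSE	NONE
XPNPEP3	OTHER	DOMINANT	FALSE	NONE
ABRAXAS1	OTHER	DOMINANT	FALSE	NONE
GEN1	OTHER	DOMINANT	FALSE	NONE
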