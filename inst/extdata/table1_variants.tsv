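# Reconstruction of the printed cohort tabulations as a variant table;
# see table1_types.tsv header for the carrier-count reconciliation.
patient_id	gene	hgvs_c	consequence	acmg_class	previously_identified	zygosity	phase	splice_offset
MALI001	BAP1	c.101del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
MALI002	BRCA2	c.102del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
MALI003	FANCA	c.103del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
MALI004	FANCC	c.104del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
MALI005	FANCD2	c.105del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
MALI006	FANCM	c.106del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
MALI007	XPC	c.107del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
OVAR001	BRCA2	c.108del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
OVAR001	BRCA1	c.109del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA003	BRCA2	c.110del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA004	BRCA2	c.111del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA005	BRCA2	c.112del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA006	BRCA2	c.113del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA007	BRCA2	c.114del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
BREA008	BRCA2	c.115del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
OVAR002	BRCA2	c.116del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
OVAR003	BRCA2	c.117del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
OVAR004	BRCA2	c.118del	FRAMESHIFT	5	TRUE	HET	UNKNOWN	 0
PROS001	BRCA2	c.119del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
PROS002	BRCA2	c.120del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
PANC001	BRCA2	c.121del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
PANC002	BRCA2	c.122del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
PANC003	BRCA1	c.123del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
UROT002	BRCA1	c.124del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
BILE001	BRCA1	c.125del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
ESOP001	BRCA1	c.126del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
ENDO001	BRCA1	c.127del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
ADEN001	BRCA1	c.128del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO003	MLH1	c.1942C>T	MISSENSE	4	FALSE	HET	UNKNOWN	 0
COLO004	MSH2	c.130del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
GAST001	MSH6	c.131del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
CUP001	PMS2	c.132del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
BREA009	CHEK2	c.1100del	FRAMESHIFT	4	FALSE	HET	UNKNOWN	 0
COLO005	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO006	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO007	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO008	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO009	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
NSCL001	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
NSCL002	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
SARC001	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
MELA001	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
HEAD001	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
HEPA001	CHEK2	c.1100del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO001	XRCC2	c.145del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO002	APC	c.146del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO010	ATR	c.147del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO011	SMAD9	c.148del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO012	BLM	c.149del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO013	MEN1	c.150del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO014	FANCI	c.151del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO015	FANCA	c.152del	FRAMESHIFT	5	FALSE	HET	UNKNOWN	 0
COLO016	RAD51D	c.153>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO017	BLM	c.154>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO018	ATR	c.155>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO019	CHEK2	c.156>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO020	BARD1	c.157>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO021	VHL	c.158>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO022	ATR	c.159>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO023	RAD51C	c.160>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO024	RB1	c.161>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO025	NBN	c.162>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO026	WRN	c.163>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
COLO027	ATM	c.164>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA001	CDKN2A	c.165>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA002	PALB2	c.166>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA010	ATR	c.167>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA011	BRIP1	c.168>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA012	APC	c.169>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA013	PALB2	c.170>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA014	BARD1	c.171>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA015	RB1	c.172>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA016	NBN	c.173>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BREA017	FANCC	c.174>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE002	BAP1	c.175>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE003	FANCA	c.176>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE004	ATM	c.177>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE005	PTEN	c.178>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE006	ATM	c.179>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE007	WRN	c.180>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE008	FAN1	c.181>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
BILE009	ERCC3	c.182>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PANC004	ERCC5	c.183>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PANC005	FANCI	c.184>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PANC006	ERCC3	c.185>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PANC007	RAD51C	c.186>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PANC008	CHEK1	c.187>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
NSCL003	FANCA	c.188>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
NSCL004	CDKN2A	c.189>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
NSCL005	STK11	c.190>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
PROS003	ATM	c.191>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
OVAR005	TP53	c.192>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
OVAR006	CHEK2	c.193>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
OVAR007	ERCC4	c.194>A	NONSENSE	5	FALSE	HET	UNKNOWN	 0
UROT001	ERCC2	c.195>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
UROT003	CHEK1	c.196>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
UROT004	BLM	c.197>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
UROT005	NBN	c.198>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
CERV001	PTEN	c.199>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
OTHE001	SEC23B	c.200>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
CUP002	FANCM	c.201>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
CUP003	TP53	c.202>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
CUP004	BRIP1	c.203>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
SARC002	CHEK2	c.204>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
SARC003	BAP1	c.205>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
HEAD002	ATM	c.206>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
NEUR001	RAD51D	c.207>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
MELA002	FANCM	c.208>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
ESOP002	CDH1	c.209>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
HEPA002	ATM	c.210>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
THYM001	SEC23B	c.211>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
RENA001	FANCM	c.212>A	SPLICE_SITE	5	FALSE	HET	UNKNOWN	-1
RENA002	CDH1	c.213>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
VULV001	BLM	c.214>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
COLO001	ERCC2	c.215>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
COLO001	FANCM	c.216>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
COLO002	BAP1	c.217>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
COLO002	XPC	c.218>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
BREA001	FANCD2	c.219>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
BREA002	BAP1	c.220>A	MISSENSE	5	FALSE	HET	UNKNOWN	 0
UROT001	NBN	c.221>A	START_LOSS	5	FALSE	HET	UNKNOWN	 0
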