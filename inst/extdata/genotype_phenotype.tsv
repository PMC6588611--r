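# Default genotype-phenotype associations (worked examples only;
# the EMERGING category is user configuration in nature).
gene	cancer_type	association
BRCA1	Breast cancer	ESTABLISHED
BRCA2	Breast cancer	ESTABLISHED
BRCA1	Ovarian cancer	ESTABLISHED
BRCA2	Ovarian cancer	ESTABLISHED
BRCA1	Pancreatic cancer	ESTABLISHED
BRCA2	Pancreatic cancer	ESTABLISHED
BRCA1	Prostate cancer	ESTABLISHED
BRCA2	Prostate cancer	ESTABLISHED
CHEK2	Breast cancer	ESTABLISHED
BAP1	Melanoma	ESTABLISHED
BAP1	Malignant mesothelioma	ESTABLISHED
APC	Colorectal cancer	ESTABLISHED
MLH1	Colorectal cancer	ESTABLISHED
MSH2	Colorectal cancer	ESTABLISHED
MSH6	Colorectal cancer	ESTABLISHED
PMS2	Colorectal cancer	ESTABLISHED
MLH1	Endometrial cancer	ESTABLISHED
MSH2	Endometrial cancer	ESTABLISHED
MSH6	Endometrial cancer	ESTABLISHED
PMS2	Endometrial cancer	ESTABLISHED
FANCM	Breast cancer	EMERGING
BLM	Colorectal cancer	EMERGING
WRN	Pancreatic cancer	EMERGING
NBN	NSCLC	EMERGING
ATM	Prostate cancer	EMERGING
FANCM	Colorectal cancer	EMERGING
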