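# Printed per-type patient/carrier counts; n_carriers adds the 4
# carriers the printed per-type counts leave unallocated (109 vs 113).
cancer_type	n_patients	n_carriers_printed	n_carriers
Colorectal cancer	141	27	27
Breast cancer	 85	16	17
Bile duct cancer	 47	 8	 9
Pancreatic cancer	 43	 7	 8
NSCLC	 33	 4	 5
Prostate cancer	 26	 3	 3
Ovarian cancer	 23	 7	 7
Urothelial cancer	 20	 5	 5
Gastric cancer	 20	 1	 1
Cervical cancer	 18	 1	 1
Others	 17	 1	 1
CUP	 16	 4	 4
Sarcoma	 14	 3	 3
Head and neck cancer	 14	 2	 2
Neuroendocrine cancer	 13	 1	 1
Malignant mesothelioma	 12	 7	 7
Melanoma	 12	 2	 2
Esophageal cancer	 11	 2	 2
SCLC	 11	 0	 0
Hepatocellular cancer	 10	 2	 2
Adrenocortical cancer	  8	 0	 0
Endometrial cancer	  8	 1	 1
Thymoma	  8	 1	 1
Renal cell carcinoma	  6	 2	 2
Adenoid cystic carcinoma	  5	 1	 1
Myoepithelial carcinoma	  4	 0	 0
Glioblastoma	  4	 0	 0
Anogenital cancer	  3	 0	 0
Germ cell cancer	  2	 0	 0
Vulvovaginal cancer	  2	 1	 1
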