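type_id	name	cancer	normal	total
BLCA	Bladder urothelial carcinoma	408	19	427
BRCA	Breast invasive carcinoma	1101	113	1214
COAD	Colon adenocarcinoma	286	41	327
HNSC	Head and neck squamous cell carcinoma	522	44	566
KICH	Kidney chromophobe	65	25	90
KIRC	Kidney renal clear cell carcinoma	534	72	606
KIRP	Kidney renal papillary cell carcinoma	291	32	323
LIHC	Liver hepatocellular carcinoma	374	50	424
LUAD	Lung adenocarcinoma	517	59	576
LUSC	Lung squamous cell carcinoma	502	51	553
PRAD	Prostate adenocarcinoma	497	52	549
THCA	Thyroid carcinoma	512	59	571
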