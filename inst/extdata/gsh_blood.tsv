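GSH_ID	Position	FDR	AF	TAD gene density	Active regions	Gene	Location	Dataset
BLD_GSH_1	chr1:150200138-150200139	0.84	0.14	NA	4_Tx,5_TxWk	ANP32E	Intron	1KG
BLD_GSH_2	chr1:198243300-198243301	1	0.11	4.94	5_TxWk	NEK7	Intron	1KG, GTEx
BLD_GSH_3	chr11:129759556-129759557	1	0.25	NA	4_Tx,5_TxWk	NFRKB	Intron	1KG
BLD_GSH_4	chr12:122722288-122722289	1	0.23	NA	4_Tx,5_TxWk	VPS33A	Intron	1KG
BLD_GSH_5	chr13:111559414-111559652	0.87	0.2	NA	4_Tx,5_TxWk	ANKRD10	Intron	1KG
BLD_GSH_6	chr15:49609604-49609605	1	0.17	10.7	5_TxWk	GALK2	Intron	1KG, GTEx
BLD_GSH_7	chr15:59169388-59169389	0.47	0.16	NA	4_Tx,5_TxWk	-	Intergenic	1KG
BLD_GSH_8	chr2:39071477-39071819	0.16	0.32	NA	4_Tx,5_TxWk	DHX57	Intron	1KG
BLD_GSH_9	chr2:223481690-223481979	0.93	0.28	NA	4_Tx,5_TxWk	FARSB	Intron	1KG
BLD_GSH_10	chr3:37361602-37361603	1	0.12	5	4_Tx,5_TxWk	GOLGA4	Intron	1KG, GTEx
BLD_GSH_11	chr3:45542662-45542663	0.13	0.36	NA	4_Tx,5_TxWk	LARS2	Intron	1KG, GTEx
BLD_GSH_12	chr3:45768351-45768676	0.26	0.38	NA	4_Tx,5_TxWk	SACM1L	Intron	1KG
BLD_GSH_13	chr4:88032137-88032469	0.76	0.58	NA	4_Tx,5_TxWk	AFF1	Intron	1KG, GTEx
BLD_GSH_14	chr6:157397700-157397701	1	0.13	NA	2_TssAFlnk,5_TxWk	ARID1B	Intron	1KG, GTEx
BLD_GSH_15	chr8:120800792-120800793	0.89	0.21	NA	4_Tx,5_TxWk	TAF2	Intron	1KG
BLD_GSH_16	chr9:100675550-100675551	n.s.	0.16	NA	4_Tx,5_TxWk	TRMO	Intron	GTEx
BLD_GSH_17	chr9:115937084-115937379	0.34	0.35	NA	4_Tx,5_TxWk	FKBP15	Intron	1KG
BLD_GSH_18	chr1:1654012-1654013	n.s.	0.15	NA	5_TxWk	CDK11A	Intron	GTEx
BLD_GSH_19	chr15:79167169-79167170	n.s.	0.12	NA	1_TssA,2_TssAFlnk	MORF4L1	Intron	GTEx
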