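GSH_ID	Position	FDR	AF	TAD gene density	Active regions	Gene	Location	Dataset
BRN_GSH_1	chr1:247027889-247027890	n.s	0.46	NA	4_Tx,5_TxWk	AHCTF1	Intron	GTEx
BRN_GSH_2	chr12:987960-987961	n.s	0.14	NA	4_Tx,5_TxWk	WNK1	Intron	GTEx
BRN_GSH_3	chr22:18283915-18283916	n.s	0.32	NA	5_TxWk	MICAL3	Intron	GTEx
BRN_GSH_4	chr4:5834890-5834891	n.s	0.22	NA	4_Tx,5_TxWk	CRMP1	Intron	GTEx
BRN_GSH_5	chr7:5553845-5553846	n.s	0.15	NA	1_TssA,2_TssAFlnk	LOC221946	Intron	GTEx
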