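miR-142-5p	ADAMTS5
miR-142-5p	BCHE
miR-142-5p	DCHS1
miR-142-5p	FIGN
miR-142-5p	FLJ10357
miR-142-5p	FLRT2
miR-142-5p	FZD7
miR-142-5p	HDAC4
miR-142-5p	MEIS2
miR-142-5p	NRP1
miR-142-5p	PDGFRA
miR-142-5p	PTPRD
miR-142-5p	RUNX1T1
miR-142-5p	SGCD
miR-142-5p	SVIL
miR-146a	C5ORF23
miR-146a	PTGFRN
miR-146a	RPESP
miR-146a	RUNX1T1
miR-146a	SRR
miR-146a	THRB
miR-26a	ATP11C
miR-26a	C7ORF42
miR-26a	CREBL2
miR-26a	DNAJA2
miR-26a	FRAT2
miR-26a	NFE2L3
miR-26a	NUP50
miR-26a	TFAP2C
miR-26a	WAPAL
miR-26a	ZNF655
miR-181c	C17ORF63
miR-181c	EPB41
miR-181c	NMT1
miR-218	NUP50
miR-218	SFMBT1
miR-218	WDR66
miR-218	WNT2B
miR-218	ZDHHC23
miR-218	ZNF313
miR-335	N4BP1
miR-335	PHTF2
miR-335	SLC45A3
miR-335	WAPAL
miR-376a	BNC1
miR-376a	MAN1C1
miR-410	AGPAT7
miR-410	DLG3
miR-410	NMT1
miR-410	OSBPL3
miR-410	RGS16
miR-410	ROD1
miR-410	ZNRF2
miR-433	PCCB
miR-433	WAPAL
miR-503	CREBL2
miR-503	DNAJA2
miR-503	KIAA1333
miR-503	MBP
miR-503	N4BP1
miR-503	NUP50
miR-503	PAFAH1B1
miR-503	RNF138
miR-503	WNT2B
miR-539	CCDC88A
miR-539	FRAT2
miR-539	LBA1
miR-539	MYCL1
miR-539	PSME3
miR-539	SNAP29
miR-539	WAPAL
miR-539	XPO6
miR-543	ARFGEF2
miR-543	ATP11C
miR-543	CSNK1D
miR-543	CTF8
miR-543	OSBPL3
miR-543	PAFAH1B1
miR-543	PPTC7
miR-543	RNF138
miR-543	SDF2L1
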