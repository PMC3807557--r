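trait	snp	maf_percent	population	mirna	element	gene
Vertical cup-disc ratio	rs12803915	21.4	EUR	miR-612	pre_mirna	NA
Pulse rate	rs6701558	11.2	ASN	miR-29b/c	promoter	NA
Schizophrenia	rs2660302	21.8	EUR	miR-137	promoter	NA
Height	rs113431232	3.4	EUR	let-7a/d/f	promoter	NA
Pigmentation	rs35407	2.2	EUR	miR-27	utr3	SLC45A2
Body mass index	rs77632545	19.9	ASN	miR-181a	utr3	ZNF169
Asthma	rs17052784	2.6	EUR	miR-140-3p	utr3	DCLK1
Plasma C-reactive protein levels	rs116971887	4.9	EUR	miR-194	utr3	SALL1
Type 1 diabetes autoantibodies	rs3842753	50.0	EUR	miR-491-5p	utr3	INS
Type 2 diabetes	rs1802295	50.0	ASN	miR-510	utr3	VPS26A
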