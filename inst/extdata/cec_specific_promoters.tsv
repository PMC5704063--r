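peak_id	gene_symbol
p@chr9:117359938..117359952,+	ATP6V1G1
p3@C4orf49	C4orf49
p@chr15:63656527..63656531,-	CA12
p3@COL4A3	COL4A3
p2@COL8A1	COL8A1
p@chr3:99354394..99354405,+	COL8A1
p2@COL8A2	COL8A2
p3@DNAJC6	DNAJC6
p8@ENO1	ENO1
p9@ENO1	ENO1
p12@ENO1	ENO1
p1@ENO1P1	ENO1P1
p@chr1:236647096..236647105,+	ENO1P1
p1@ENST00000354541	ENST00000354541
p1@ENST00000357401	ENST00000357401
p5@ERG	ERG
p1@FGF10	FGF10
p3@FGF7	FGF7
p6@FGF7	FGF7
p10@FGF7	FGF7
p@chr2:217526641..217526672,+	IGFBP2
p3@ITGBL1	ITGBL1
p2@LMX1B	LMX1B
p1@MIR184	MIR184
p1@MSMP	MSMP
p3@MSMP	MSMP
p1@PITX2	PITX2
p2@PITX2	PITX2
p3@PITX2	PITX2
p8@PITX2	PITX2
p3@POU6F2	POU6F2
p@chr7:39018373..39018384,+	POU6F2
p9@PTGDS	PTGDS
p10@PTGDS	PTGDS
p@chr9:139874657..139874682,-	PTGDS
p3@SHC4	SHC4
p5@SHC4	SHC4
p2@SLC4A11	SLC4A11
p7@SLC4A4	SLC4A4
p1@TFAP2B	TFAP2B
p2@TFAP2B	TFAP2B
p3@TFAP2B	TFAP2B
p9@TFAP2B	TFAP2B
p4@TSPAN6	TSPAN6
p6@ZFHX4	ZFHX4
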