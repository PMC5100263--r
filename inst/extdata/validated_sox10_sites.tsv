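element	locus	assembly	chrom	browser_start	browser_end	sequence	spacer	active_required
SOX10-CCS-01	PAX7	hg18	chr1	18854300	18855055	ACAAACTCATTAAACTTGT	CTCATTAAA	no
SOX10-CCS-13	SOX6	hg18	chr11	16334301	16335278	ACAATCAAGCATTGT	CAAGC	yes
SOX10-CCS-18	SOX5	hg18	chr12	24058988	24059872	ACAAAAATGTATTGT	AATGT	no
SOX10-CCS-19	SOX5	hg18	chr12	24059397	24060164	ACACAGAACATTATTGT	GAACATT	yes
SOX10-CCS-39	TCF7L2	hg18	chr10	114894980	114895808	ACAATCCCCAAGATTTTTGT	CCCCAAGATT	no
SOX10-CCS-43	BCAS3	hg18	chr17	56683905	56684657	ACACATTAATAACGTTTTGT	TTAATAACGT	no
SOX10-CCS-51	NFIB	hg18	chr9	14299332	14299796	ACAATCTGTTCTTTGTGT	CTGTTCTT	yes
Notch1-R1	NOTCH1	rn5	chr3	9307836	9308296	ACAATGGGGCCTCTGT	GGGGCC	yes
Notch1-R2	NOTCH1	rn5	chr3	9308175	9309096	ACAATCGGCTTTGT	CGGC	no
Hmga2-R1	HMGA2	rn5	chr7	65390088	65391287	CTTAGACACAGCACTT		no
Hmga2-R2	HMGA2	rn5	chr7	65427912	65428606	ACACAGGCCCCTCTTTGT	GGCCCCTC	yes
Hes1-R1	HES1	rn5	chr11	77415315	77415779	TGTGTGAGCGCCATGTGT	GAGCGCCA	no
Mycn-R1	MYCN	rn5	chr6	51229947	51230533	ACAATGGCCTCTTTCTACAGACAAT	GGCCTC	yes
Id4-R1	ID4	rn5	chr17	18701460	18702118	ACAAAAACAGCAGTAAATGGAGGCCTTTGT	AACAGCAGTAAATGGAGGCC	yes
Id2-R1	ID2	rn5	chr6	53090794	53091254	ACAAGAAACACATTGT	AAACAC	yes
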