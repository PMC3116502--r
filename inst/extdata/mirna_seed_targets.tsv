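mirna	target_motif	opsin	conserved_in
miR-725	TGACTGAG	SWS1	GA
miR-217	ATGCAGTA	SWS2B	GA
miR-181a	AGAATGTA	SWS2A	DR
miR-23b	TATGTGAA	RH2B	TR
miR-96	TTGCCAAA	RH2A	OL
miR-182a	TTGCCAAA	RH2A	OL
miR-728	TTTAGTAA	LWS	GA,TN,TR
miR-722	GCAAAAAA	LWS	TR
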