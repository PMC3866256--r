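index	equation	genes
3115	[x]:h2o+prpncoa→3hpcoa	EHHADH
3161	[c]:pi+uri ⇆ r1p+ura	UPP1 UPP2
3573	[c]:h+nadh+q10→nad+q10h2	TXNRD1
3474	[m]:fad+succ ⇆ fadh2+fum	SDHD SDHC SDHB SDHA
3511	[m]:coa+tetpent6crn→crn+tetpent6coa	CPT2
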