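interval	gene	chr	start_bp	end_bp	size_bp	n_snps	label
1	ACSM5	3	18557492	53699303	35141811	58	cis/trans
2	ACSS2	6	17315441	17502570	187129	2	trans
3	ACSS2	7	111283606	112227872	944266	8	trans
4	ACSS2	13	156576634	156644710	68076	2	trans
5	ATF3	1	181624438	181702614	78176	3	trans
6	ATF3	13	177313258	177546824	233566	2	trans
7	DGAT2	16	2764727	2779416	14689	2	trans
8	FOS	10	493510	493510	0	2	trans
9	FOS	11	8855571	19677423	10821852	3	trans
10	IGF2	2	1000000	25964207	24964207	104	cis/trans
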