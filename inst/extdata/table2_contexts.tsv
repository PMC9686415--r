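sample_id	mcg	mchg	mchh	share_cg_pct	share_chg_pct	share_chh_pct
CGC1	26421894	237327	906008	95.85	0.86	3.29
CGC2	26274536	236120	889033	95.89	0.86	3.25
CGC3	26435931	231192	924601	95.81	0.84	3.35
OGC1	26275999	202362	810165	96.29	0.74	2.97
OGC2	26116512	208134	835541	96.16	0.77	3.08
OGC3	26564745	201726	790038	96.40	0.73	2.87
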