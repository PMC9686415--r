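sample_id	clean_reads	clean_bases_gb	clean_ratio_pct	mapped_reads	mapping_rate_pct	uniquely_mapped_reads	unique_rate_pct	conversion_rate_pct
CGC1	350174586	26.50	95.97	325098027	92.84	309905822	88.50	99.05
CGC2	320220488	24.01	97.46	298520528	93.22	284589492	88.87	99.05
CGC3	334573094	25.02	96.13	311321665	93.05	296207252	88.53	99.02
OGC1	351592970	26.01	96.50	327220334	93.07	312048923	88.75	99.06
OGC2	318216916	23.70	96.37	296111680	93.05	282023990	88.63	99.05
OGC3	393144866	28.30	96.78	365808412	93.05	348424438	88.62	99.05
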