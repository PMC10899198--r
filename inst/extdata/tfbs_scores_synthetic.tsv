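# SYNTHETIC stand-in for per-variant transcription-factor binding-site
# delta scores. The variant x TF pairs and the allele-specific FDR tier
# are the published high-confidence predictions for the 27 allele-specific
# enhancer variants; the numeric scores themselves were not published, so
# each retained pair carries a synthetic placeholder magnitude of 0.9
# (negative = predicted disruption; the two variants whose direction the
# study discusses, rs11646653/ARNT and rs3739034/GATA factors, are
# negative as described).
variant_id	tf_name	score	fdr_tier
rs2746478	GLIS3	-0.9	fdr_lt_0.05
rs2746478	ZIC5	-0.9	fdr_lt_0.05
rs6689005	SREBF1	-0.9	fdr_lt_0.05
rs6689005	EHF	-0.9	fdr_lt_0.05
rs6689005	ELF1	-0.9	fdr_lt_0.05
rs6689005	ELF4	-0.9	fdr_lt_0.05
rs6689005	ERF	-0.9	fdr_lt_0.05
rs6689005	ERG	-0.9	fdr_lt_0.05
rs6689005	ETS1	-0.9	fdr_lt_0.05
rs6689005	ETS2	-0.9	fdr_lt_0.05
rs6689005	ETV1	-0.9	fdr_lt_0.05
rs6689005	ETV2	-0.9	fdr_lt_0.05
rs6689005	FLI1	-0.9	fdr_lt_0.05
rs6689005	GABPA	-0.9	fdr_lt_0.05
rs6689005	IKZF1	-0.9	fdr_lt_0.05
rs6689005	STAT2	-0.9	fdr_lt_0.05
rs16830920	HSF2	-0.9	fdr_lt_0.05
rs3739034	EOMES	-0.9	fdr_lt_0.05
rs3739034	GATA1	-0.9	fdr_lt_0.05
rs3739034	GATA2	-0.9	fdr_lt_0.05
rs3739034	GATA4	-0.9	fdr_lt_0.05
rs3739034	GATA6	-0.9	fdr_lt_0.05
rs6719061	PRDM14	-0.9	fdr_lt_0.05
rs6719061	TRPS1	-0.9	fdr_lt_0.05
rs812383	NKX3-2	-0.9	fdr_lt_0.05
rs812383	TBX19	-0.9	fdr_lt_0.05
rs78222414	ZBTB26	-0.9	fdr_lt_0.05
rs78222414	ZBTB6	-0.9	fdr_lt_0.05
rs6770112	ZNF135	-0.9	fdr_lt_0.05
rs6449345	FOXH1	-0.9	fdr_lt_0.05
rs112525610	EOMES	-0.9	fdr_lt_0.05
rs112525610	ZIC2	-0.9	fdr_lt_0.05
rs62362545	HOXC10	-0.9	fdr_lt_0.05
rs62362545	POU2F1	-0.9	fdr_lt_0.05
rs113661575	ZNF135	-0.9	fdr_lt_0.05
rs4700390	E2F1	-0.9	fdr_lt_0.05
rs4700390	E2F4	-0.9	fdr_lt_0.05
rs3815082	STAT5A	-0.9	fdr_lt_0.05
rs3815082	STAT5B	-0.9	fdr_lt_0.05
rs3815082	ZNF189	-0.9	fdr_lt_0.05
rs2723264	BHLHA15	-0.9	fdr_lt_0.05
rs2723264	ISL1	-0.9	fdr_lt_0.05
rs2723264	NEUROD1	-0.9	fdr_lt_0.05
rs2723264	NEUROG2	-0.9	fdr_lt_0.05
rs2723264	MAFB	-0.9	fdr_lt_0.05
rs11071650	ZBTB6	-0.9	fdr_lt_0.05
rs11071650	ATF1	-0.9	fdr_lt_0.05
rs11071650	ESR2	-0.9	fdr_lt_0.05
rs11071650	FOS	-0.9	fdr_lt_0.05
rs11071650	FOSL1	-0.9	fdr_lt_0.05
rs11071650	FOSL2	-0.9	fdr_lt_0.05
rs11071650	JUN	-0.9	fdr_lt_0.05
rs11071650	NFE2	-0.9	fdr_lt_0.05
rs11071650	NFE2L2	-0.9	fdr_lt_0.05
rs11071650	RORC	-0.9	fdr_lt_0.05
rs7161856	SIX2	-0.9	fdr_lt_0.05
rs11646653	ARNT	-0.9	fdr_lt_0.05
rs11646653	BHLHE40	-0.9	fdr_lt_0.05
rs11646653	BHLHE41	-0.9	fdr_lt_0.05
rs11646653	ZNF75D	-0.9	fdr_lt_0.05
rs11860998	PRDM14	-0.9	fdr_lt_0.05
rs55749333	RXRA	-0.9	fdr_lt_0.05
rs8121449	ZNF416	-0.9	fdr_lt_0.05
rs6084993	SIX2	-0.9	fdr_lt_0.05
rs6084993	TEAD1	-0.9	fdr_lt_0.05
rs6084993	TEAD2	-0.9	fdr_lt_0.05
rs6084993	TEAD3	-0.9	fdr_lt_0.05
rs6084993	TEAD4	-0.9	fdr_lt_0.05
rs6084993	NR1D1	-0.9	fdr_lt_0.05
rs6084993	PPARG	-0.9	fdr_lt_0.05
rs6084993	ZNF135	-0.9	fdr_lt_0.05
rs208376	POU2F1	-0.9	fdr_lt_0.05
rs208376	POU2F2	-0.9	fdr_lt_0.05
rs208376	POU2F3	-0.9	fdr_lt_0.05
rs208376	POU3F1	-0.9	fdr_lt_0.05
rs12755229	NFATC1	-0.9	fdr_lt_0.1
rs12755229	NFATC2	-0.9	fdr_lt_0.1
rs12755229	STAT3	-0.9	fdr_lt_0.1
rs12755229	ZBTB26	-0.9	fdr_lt_0.1
rs10929159	ESR1	-0.9	fdr_lt_0.1
rs10929159	ESR2	-0.9	fdr_lt_0.1
rs34378	ZFP57	-0.9	fdr_lt_0.1
rs10471496	ZNF692	-0.9	fdr_lt_0.1
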