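# Published per-group overlap counts between MPRA elements and epigenetic
# annotation classes (ChromHMM promoter/enhancer states, DNase I
# hypersensitivity peaks, ENCODE ChIP-seq protein binding sites), as
# printed in the source study's overlap table. Group sizes derived from
# the printed counts and percentages.
group	size	promoter	enhancer_state	dnase	protein_binding
allele_specific	27	1	16	9	2
general	91	22	46	37	23
background	5094	856	2765	1529	616
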