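# Gene deserts containing tissue-specific superenhancers (hg19 labels kept
# as opaque text). Columns: chrom, start, end, comma-joined validated-element
# ids with positive craniofacial staining.
chr3	126756235	127291911	mm1516
chr5	90679176	92919042	hg952,hg1153
chr6	18469105	19837616	hg1052
chr7	25268105	26191859	hg1600,mm402,mm403,mm404,mm405,mm406
chr8	142528837	143293440	mm1584
chr10	35931206	37414715	hg1567
chr16	65160015	66400524	mm40
chr16	73093597	74330672	hg1612
chr17	68176189	70117160	mm628,mm634,mm635
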