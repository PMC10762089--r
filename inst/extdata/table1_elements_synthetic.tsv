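# SYNTHETIC validated-element catalog: element ids and their craniofacial
# positivity follow the published desert table; element coordinates are NOT
# published and were constructed inside the corresponding desert interval.
# The four syn_neg elements are constructed tested-but-negative elements in
# the chr7 desert (two positive in another tissue, two negative everywhere).
# Columns: element_id, chrom, start, end, comma-joined positive tissues
# ("." = tested with no positive tissue).
mm1516	chr3	126806235	126808235	craniofacial
hg952	chr5	90729176	90731176	craniofacial
hg1153	chr5	90779176	90781176	craniofacial,limb
hg1052	chr6	18519105	18521105	craniofacial
hg1600	chr7	25318105	25320105	craniofacial
mm402	chr7	25418105	25420105	craniofacial
mm403	chr7	25518105	25520105	craniofacial
mm404	chr7	25618105	25620105	craniofacial
mm405	chr7	25718105	25720105	craniofacial,heart
mm406	chr7	25818105	25820105	craniofacial
syn_neg1	chr7	25918105	25920105	limb
syn_neg2	chr7	25968105	25970105	heart
syn_neg3	chr7	26018105	26020105	.
syn_neg4	chr7	26068105	26070105	.
mm1584	chr8	142578837	142580837	craniofacial
hg1567	chr10	35981206	35983206	craniofacial
mm40	chr16	65210015	65212015	craniofacial
hg1612	chr16	73143597	73145597	craniofacial
mm628	chr17	68226189	68228189	craniofacial
mm634	chr17	68276189	68278189	craniofacial
mm635	chr17	68326189	68328189	craniofacial
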