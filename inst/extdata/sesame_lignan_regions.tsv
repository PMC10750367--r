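# 99%-level candidate QTL regions for lignan content in the Goenbaek x Gomazou
# sesame RIL cross, one block per parental consensus orientation.
# Single-position entries denote one significant 50 kb scan step; their end is
# start + 50,000. The chr11 Goenbaek end was printed with a truncated digit
# group ("2,100,00"); end carries the reconstruction 2,100,000 implied by the
# stated 1.6 Mb span, end_printed the string as printed.
orientation	chrom	start	end	end_printed	index_low	index_high	delta
Goenbaek	chr1	3950000	4000000		0.9305	0.284	-0.6465
Goenbaek	chr1	5650000	10100000	10100000	0.9044	0.2155	-0.6889
Goenbaek	chr1	11400000	11450000		0.8871	0.2597	-0.6273
Goenbaek	chr1	11600000	11750000	11750000	0.9123	0.3052	-0.6071
Goenbaek	chr1	12850000	12900000	12900000	0.8936	0.264	-0.6285
Goenbaek	chr1	15100000	16750000	16750000	0.9774	0.2078	-0.7696
Goenbaek	chr2	14850000	15250000	15250000	0.8667	0.2131	-0.6536
Goenbaek	chr3	23150000	23600000	23600000	0.9971	0.3881	-0.609
Goenbaek	chr6	15100000	16050000	16050000	0.3565	0.9978	0.6414
Goenbaek	chr9	6000000	6350000	6350000	0.9549	0.3348	-0.6201
Goenbaek	chr9	6550000	6700000	6700000	0.9558	0.3378	-0.6181
Goenbaek	chr11	500000	2100000	2,100,00	0.8743	0.0206	-0.8537
Gomazou	chr1	3950000	4000000		0.081	0.7174	0.6364
Gomazou	chr1	5650000	10100000	10100000	0.0992	0.7779	0.6787
Gomazou	chr1	11400000	11450000		0.1228	0.7369	0.6142
Gomazou	chr1	11600000	11650000		0.088	0.6968	0.6087
Gomazou	chr1	12850000	12900000	12900000	0.1111	0.7391	0.628
Gomazou	chr1	15100000	16750000	16750000	0.0243	0.7923	0.768
Gomazou	chr2	14950000	15250000	15250000	0.1358	0.7853	0.6495
Gomazou	chr3	23150000	23600000	23600000	0.003	0.6196	0.6166
Gomazou	chr6	14600000	16500000	16500000	0.8129	0.021	-0.792
Gomazou	chr11	500000	2100000	2100000	0.1277	0.99	0.8623
Gomazou	chr11	2450000	3150000	3150000	0.8427	0.1523	-0.6904
Gomazou	chr12	14350000	15750000	15750000	0.7222	0.0054	-0.7167
Gomazou	chr13	2550000	2600000	2600000	0.2645	0.869	0.6045
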