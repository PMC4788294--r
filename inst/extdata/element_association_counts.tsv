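# Published association counts between unselected LOH breakpoints and 19
# yeast genomic element classes, composite of 43 analyzed genomes on an
# 11.6-Mb array universe: per-genome element count, totals, expected and
# observed counts inside/outside the breakpoint association windows, and
# the published chi-square p-value.
class_name	n_per_genome	total	expected_in	expected_out	observed_in	observed_out	p_published
tRNA genes	275	11782	82	11700	77	11705	0.61
ARS elements	337	13244	92	13152	69	13175	0.019
snRNA and snoRNA genes	83	3569	25	3544	25	3544	1
ncRNA genes	14	602	4	598	6	596	0.45
Ty elements	50	2064	14	2050	12	2052	0.69
Solo long-terminal repeats	231	9460	66	9394	79	9381	0.12
Centromeres	16	688	5	683	3	685	0.5
Palindromic sequences	611	24553	170	24383	159	24394	0.42
G4 sequences (motif 1)	636	23392	162	23230	139	23253	0.08
Highly-transcribed genes	330	14190	99	14091	86	14104	0.21
Weakly-transcribed genes	332	13416	93	13323	118	13298	0.01
Binding sites for Rrm3p	115	4816	34	4782	37	4779	0.67
Regions with high levels of gamma-H2AX	697	27262	189	27073	234	27028	0.0012
Replication-termination sequences	71	3053	21	3032	25	3028	0.45
G4 sequences (motif 2)	38	1075	7	1068	6	1069	0.84
G4 sequences (motif 3)	153	3741	26	3715	21	3720	0.37
Regions of high GC content	164	6235	43	6192	50	6185	0.32
Ume6p binding sites	72	3096	21	3075	17	3079	0.45
Sum1p binding sites	37	1591	11	1580	9	1582	0.65
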