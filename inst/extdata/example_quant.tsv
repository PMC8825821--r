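peptide_id	snp_id	n_psm	ch01	ch02	ch03	ch04
pep1	chr1:100:A:G	2	18000	250000	990000	17000
pep2	chr1:200:C:T	1	410000	15800	16900	950000
pep3	chr1:300:G:A	1	880000	390000	.	420000
pep4	chr2:250:G:C	3	16500	17500	405000	0
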