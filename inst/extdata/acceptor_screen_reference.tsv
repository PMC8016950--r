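rank	q	rmsd	n_align	n_residue	seq_identity	source_tag	pdb_id
1	0.85	0.89	220	229	53	Humanized	1L7I
2	0.85	1.00	222	230	54	Human	5ILC
3	0.84	1.01	222	232	50	Human	5I8C
4	0.84	0.99	218	225	54	Human	4KQ3
5	0.83	1.07	222	231	57	unpublished	3NCJ
6	0.83	1.03	220	229	54	Human	3KYM
7	0.83	1.07	218	223	52	Humanized	5TDO
8	0.83	1.08	222	231	57	unpublished	3NAA
9	0.83	1.03	220	229	57	Human	5V7R
10	0.82	1.10	222	231	56	unpublished	3NAB
11	0.82	1.09	222	232	54	Human	4NRY
12	0.82	1.17	221	226	53	Humanized	1T3F
13	0.82	1.07	223	235	60	Human	5ILL
14	0.82	1.13	223	232	54	Human	4NRY
15	0.82	1.07	217	223	51	Human	5TDN
16	0.82	1.18	222	228	57	Human	5IL6
17	0.82	1.07	222	234	56	Human	5IT2
18	0.82	1.12	221	230	50	Humanized	1AD0
19	0.82	1.15	221	229	53	Human	4LLU
20	0.81	1.22	221	226	48	Human	2JIX
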