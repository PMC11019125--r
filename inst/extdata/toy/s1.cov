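chr1	100	100	50	5	5
chr1	200	200	50	5	5
chr1	300	300	50	5	5
chr1	400	400	50	5	5
chr1	500	500	50	5	5
chr1	600	600	50	5	5
chr1	700	700	50	5	5
chr1	800	800	50	5	5
chr1	900	900	50	5	5
chr1	1000	1000	50	5	5
chr1	1100	1100	50	5	5
chr1	1200	1200	50	5	5
chr1	1300	1300	50	5	5
chr1	1400	1400	50	5	5
chr1	1500	1500	50	2	2
chr1	1600	1600	50	2	2
chr2	100	100	95	19	1
chr2	200	200	5	1	19
chrM	100	100	50	5	5
scaffold_1	100	100	50	5	5
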