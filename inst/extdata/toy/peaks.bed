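chr1	1000	1500	toyPeak01	0	.	250
chr1	6000	6500	toyPeak02	0	.	250
chr1	11000	11500	toyPeak03	0	.	250
chr1	16000	16500	toyPeak04	0	.	250
chr1	21000	21500	toyPeak05	0	.	250
chr1	26000	26500	toyPeak06	0	.	250
chr1	31000	31500	toyPeak07	0	.	250
chr1	36000	36500	toyPeak08	0	.	250
chr1	41000	41500	toyPeak09	0	.	250
scaffold_1	46000	46500	toyPeak10	0	.	250
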