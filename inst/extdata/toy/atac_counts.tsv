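feature	s1	s2	s3
toyPeak01	30	30	30
toyPeak02	30	30	30
toyPeak03	30	30	30
toyPeak04	30	30	30
toyPeak05	30	30	30
toyPeak06	30	30	30
toyPeak07	20	20	20
toyPeak08	5	5	5
toyPeak09	10	12	9
toyPeak10	100	100	100
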