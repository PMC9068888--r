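robustness	class	five_utr	recoding	synonymous	splice_junction	intron	three_utr
robust	neural	1646	13965	4854	78	8728	9467
robust	ubiq_high	56	206	28	10	1049	1022
robust	ubiq_low	101	414	231	6	537	609
robust	ubiq_med	322	519	355	22	4924	5327
robust	other	82	189	60	3	1500	210
not_robust	neural	1024	8303	4641	42	3568	6175
not_robust	ubiq_high	0	0	0	0	0	0
not_robust	ubiq_low	4368	53182	30971	268	11099	30273
not_robust	ubiq_med	60	139	123	11	642	1518
not_robust	other	103	165	71	4	605	142
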