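gene	sample	group	ct	detected
Gdf11	s1	control	21.100000000000001	TRUE
Gdf11	s2	control	21.300000000000001	TRUE
Gdf11	s3	test	22.399999999999999	TRUE
Gdf11	s4	test	22.600000000000001	TRUE
Ppia	s1	control	18.199999999999999	TRUE
Ppia	s2	control	18.199999999999999	TRUE
Ppia	s3	test	18.199999999999999	TRUE
Ppia	s4	test	18.199999999999999	TRUE
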