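sample	events	mean_length_kb	mean_sites	loh_rate
13-507	1	231	264	1.66e-6
14-465	0	NA	NA	NA
20-479	5	90	248	8.36e-6
26-460	6	404	578	2.40e-5
27-508	1	412	1595	1.02e-5
28-503	8	397	1001	5.60e-5
33-427	5	38	164	6.05e-6
48-504	22	338	869	1.36e-4
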