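sample	generations	coverage	snm	indel	mu_snm	mu_indel
13-507	507	79	112	6	1.26e-9	0.68e-10
14-465	465	135	98	3	1.17e-9	0.36e-10
20-479	479	57	246	33	3.08e-9	4.13e-10
26-460	460	84	194	27	2.40e-9	3.33e-10
27-508	508	86	164	21	1.83e-9	2.34e-10
28-503	503	49	182	18	2.23e-9	2.21e-10
33-427	427	85	208	24	2.76e-9	3.19e-10
48-504	504	56	259	48	3.11e-9	5.77e-10
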