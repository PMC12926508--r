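label	type	count	rate
C:G>T:A	transition	497	18.53e-10
A:T>G:C	transition	332	8.59e-10
A:T>T:A	transversion	215	5.54e-10
C:G>A:T	transversion	186	6.93e-10
A:T>C:G	transversion	144	3.71e-10
C:G>G:C	transversion	89	3.29e-10
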