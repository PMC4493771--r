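group	subcluster	n
I	1A	172
I	1B	261
I	1C	55
I	1D	776
I	1E	434
I	1F	169
II	all	148
III	all	258
IV	all	457
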