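library	total_reads	mapped_reads	unique_match_reads
CK0	12009135	10461248	4491205
CK1	11530205	10022661	4400232
CK2	10568766	9161789	4003146
CK3	10862567	9472399	4147267
ETH1	12477700	10921142	4756944
ETH2	11905084	10401413	4516857
ETH3	12284279	10628560	4693781
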