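quantity	n
responsive	6167
go_annotated	3249
go_branch	2471
kegg_branch	2344
candidates	2730
day1_up	723
day1_down	1601
later_up	299
later_down	107
up_total	1022
down_total	1708
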