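category	part	n
hormone	group_I	124
hormone	group_II	16
hormone	group_III	17
hormone	group_IV	38
tf	up	51
tf	down	76
cell_wall	biosynthesis	56
cell_wall	degradation	104
cell_wall	loosening	21
cell_wall	modification	27
ros	up	39
ros	down	49
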