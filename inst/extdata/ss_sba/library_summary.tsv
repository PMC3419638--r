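key	value
n_clones	36864
n_plates	96
n_sampled_clones	192
mean_insert_bp	125000
min_insert_bp	29000
max_insert_bp	293000
n_hq_bes	378
mean_bes_length_bp	944
min_bes_length_bp	312
chloroplast_contaminated_clones	1
mitochondria_contaminated_clones	0
genome_size_low_bp	760000000
genome_size_high_bp	930000000
genome_size_revised_bp	580000000
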