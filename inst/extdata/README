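core_network.yaml: the default PDH/PC/ME1 atom-transition network,
as written by write_network_config(build_core_network()).

example_raw_protein_mids_synthetic.csv: a small synthetic raw (uncorrected)
protein-hydrolysate MID table generated by
generate_dataset(preset("pc_ko", seed = 42, n_replicates = 1)); suitable
for trying read_mid_table() and correct_natural_abundance().
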