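# Demo trial for the analysis scripts: a scaled-down two-bed alpha-lattice
# wheat trial (50 genotypes, 2 replicates, 10 incomplete blocks, 2 m plots)
# at 3 cm ground sampling distance, with the default canopy and measurement
# noise levels. The full-size defaults (150 genotypes, 30 blocks, 1.7 cm GSD)
# are what simulation_config() gives with no arguments.
seed: 42
n_genotypes: 50
n_replicates: 2
n_blocks_per_rep: 10
plot_length_m: 2
cell_size_m: 0.03
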