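name: "null"
n_populations: 8
n_loci: 20000
n_individuals_per_pop: 10
f_per_population: [0.35, 0.40, 0.05, 0.08, 0.15, 0.22, 0.30, 0.50]
ancestral_freq_dist:
  dist: beta
  shape1: 0.5
  shape2: 2.0
pool_coverage_mean: 20
discovery_panel: ~
reference_populations: [pop3, pop4]
ascertainment_maf_min: 0.0
ld_block_size: 20
ld_decay: 0.0
n_templates: 4
missing_rate: 0.0
n_chromosomes: 5
seed: 1
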