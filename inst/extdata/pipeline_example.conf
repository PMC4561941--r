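# example pipeline configuration (key: value per line)
seed_topic: Carcinoma of bladder
kld_threshold: 0.01
alpha: 0.7
walk_tolerance: 1e-6
walk_max_iter: 50
max_depth: 4
idf_quantile: 0.05
top_n: 10
target_semtypes: gngm
walk_variant: restart
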