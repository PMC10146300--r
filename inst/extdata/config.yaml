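# Default pipeline configuration. Keys mirror the arguments of
# pipeline_config(); marker times are fixed protocol constants (20 us,
# 300 us, 2 ms, 30 ms, 1000 ms) and are not configurable.
out_dir: "ojip_out"
control_label: "MT"
alpha: 0.05
alpha2: 0.01
seed: 7
n_replicates: 3
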