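# Example pipeline configuration for `ctoam run --config example_run.yaml`
# Any field of ctoam_config() may be overridden; unset fields keep defaults.
n_per_group: 15
bones: [distal_femur, tibial_plateau]
sides: [right, left]
noise_sd_hu: 30
threshold_hu: 901
min_area_mm2: 25
alpha: 0.05
seed: 1
write_png: true
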